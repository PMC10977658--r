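# Independent brute-force oracles used to pin the fast implementations.

# Exhaustive two-segment step-fit changepoint: minimize total SSE over all
# splits by direct recomputation (O(n^2)). Returns the 1-based index of the
# first post-step frame.
oracle_changepoint <- function(y) {
  n <- length(y)
  sse <- vapply(seq_len(n - 1L), function(k) {
    pre <- y[seq_len(k)]
    post <- y[(k + 1L):n]
    sum((pre - mean(pre))^2) + sum((post - mean(post))^2)
  }, numeric(1))
  which.min(sse) + 1L
}

# Closed-form right-censored exponential MLE.
oracle_censored_exp_mle <- function(durations, open) {
  sum(durations) / sum(!open)
}

# Small two-channel scenario for fast imaging tests.
small_scenario <- function(n_events = 25, seed = 1, duration = 100,
                           preset = "thp1_basal", ...) {
  make_scenario(preset, seed = seed,
                overrides = list(n_events = n_events,
                                 movie_duration = duration,
                                 field_width_px = 128,
                                 field_height_px = 128, ...))
}

# Match detected positions to truth positions within tol px; returns the
# number of truth entries with at least one match and the number of
# detections matching nothing (false positives), one-to-one greedy.
match_positions <- function(det_x, det_y, true_x, true_y, tol = 2) {
  used <- rep(FALSE, length(det_x))
  hits <- 0L
  for (i in seq_along(true_x)) {
    d2 <- (det_x - true_x[i])^2 + (det_y - true_y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && d2[j] <= tol^2) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall_hits = hits, false_pos = sum(!used))
}
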