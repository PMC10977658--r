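#' Detect probe rupture in a kymograph trace by two-segment step fit
#'
#' Fits every possible two-segment piecewise-constant model (high plateau
#' followed by low plateau) to the intensity trace and places the
#' changepoint at the split minimizing the summed squared error. The step is
#' accepted when the drop (pre-step median minus post-step mean) exceeds
#' `threshold_fraction` of the pre-step median; otherwise the trace is
#' reported censored (no rupture seen). An all-constant trace is censored,
#' not an error.
#'
#' The search is exhaustive over all n-1 splits, computed in O(n) with
#' cumulative sums, so the estimator is deterministic and directly
#' comparable to a brute-force oracle.
#'
#' @param trace A data.frame with columns `frame_time_s` and `intensity`
#'   (one probe), or a numeric intensity vector with `times` supplied.
#' @param threshold_fraction Minimum accepted drop as a fraction of the
#'   pre-step median.
#' @param times Frame times when `trace` is a bare numeric vector.
#' @return A list with `censored` (logical), and when a rupture is found
#'   `rupture_time` (time of the first post-step frame), `index` (its
#'   1-based frame index) and `drop` (step size in intensity units).
#' @export
detect_rupture <- function(trace, threshold_fraction = 0.5, times = NULL) {
  if (is.data.frame(trace)) {
    y <- trace$intensity
    tt <- trace$frame_time_s
  } else {
    y <- as.numeric(trace)
    tt <- if (is.null(times)) seq_along(y) else times
  }
  n <- length(y)
  if (n < 5L) stop("trace must have at least 5 frames", call. = FALSE)
  assert_fraction(threshold_fraction, "threshold_fraction")

  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  k <- seq_len(n - 1L)                      # last frame of the pre segment
  sse_pre <- cs2[k] - cs[k]^2 / k
  s_post <- cs[n] - cs[k]
  s2_post <- cs2[n] - cs2[k]
  m <- n - k
  sse_post <- s2_post - s_post^2 / m
  sse <- sse_pre + sse_post
  best <- which.min(sse)

  pre_med <- stats::median(y[seq_len(best)])
  post_mean <- (cs[n] - cs[best]) / (n - best)
  drop <- pre_med - post_mean
  if (!is.finite(drop) || pre_med <= 0 || drop < threshold_fraction * pre_med) {
    return(list(censored = TRUE))
  }
  list(censored = FALSE, rupture_time = tt[best + 1L], index = best + 1L,
       drop = drop)
}

#' Force at a given time of a pull record
#'
#' Linear interpolation of the force channel; times at a sample return that
#' sample's force, midpoints the mean of the neighbors.
#'
#' @param pull A `PullRecord`.
#' @param rupture_time Time in seconds, within the record's time range.
#' @return Force in pN (vectorized over `rupture_time`).
#' @export
rupture_force <- function(pull, rupture_time) {
  stopifnot(inherits(pull, "PullRecord"))
  if (any(rupture_time < min(pull$time) | rupture_time > max(pull$time))) {
    stop("rupture_time outside the pull record", call. = FALSE)
  }
  stats::approx(pull$time, pull$force, xout = rupture_time,
                ties = "ordered")$y
}

#' Gaussian fit of a rupture-force distribution
#'
#' Default is maximum likelihood on the raw forces (histogram-free; mean and
#' MLE standard deviation). `gaussian_lsq_histogram` bins the forces
#' (Freedman-Diaconis width) and least-squares fits a Gaussian profile to
#' the counts, for parity with histogram-based reports. Censored events are
#' excluded from the fit and their count reported.
#'
#' @param events Data.frame with columns `rupture_force` and `censored`
#'   (as produced by [simulate_pull()] or [calibrate_pulls()]), or a bare
#'   numeric vector of forces.
#' @param fit_kind `"gaussian_mle"` or `"gaussian_lsq_histogram"`.
#' @return A list of class `ForceDistributionFit`: `mean`, `sd`, `n`
#'   (uncensored events fitted), `n_censored`, `fit_kind`.
#' @export
fit_force_distribution <- function(events,
                                   fit_kind = c("gaussian_mle",
                                                "gaussian_lsq_histogram")) {
  fit_kind <- match.arg(fit_kind)
  if (is.data.frame(events)) {
    f <- events$rupture_force[!events$censored]
    n_cens <- sum(events$censored)
  } else {
    f <- as.numeric(events)
    f <- f[is.finite(f)]
    n_cens <- 0L
  }
  if (length(f) < 10L) {
    stop(sprintf(paste0("only %d uncensored rupture events; at least 10 are",
                        " needed for a stable Gaussian fit - collect more",
                        " pulls"), length(f)), call. = FALSE)
  }
  if (fit_kind == "gaussian_mle") {
    mu <- mean(f)
    sdv <- sqrt(mean((f - mu)^2))
  } else {
    bw <- 2 * stats::IQR(f) / length(f)^(1 / 3)
    if (bw <= 0) bw <- 1
    breaks <- seq(min(f) - bw, max(f) + bw, by = bw)
    h <- graphics::hist(f, breaks = breaks, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$counts)
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
      start = list(A = max(df$y), mu = mean(f), s = stats::sd(f)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    mu <- unname(cf["mu"])
    sdv <- abs(unname(cf["s"]))
  }
  structure(list(mean = mu, sd = sdv, n = length(f), n_censored = n_cens,
                 fit_kind = fit_kind),
            class = "ForceDistributionFit")
}

#' @export
print.ForceDistributionFit <- function(x, ...) {
  cat(sprintf("Rupture force %.2f +/- %.2f pN (N = %d, %d censored; %s)\n",
              x$mean, x$sd, x$n, x$n_censored, x$fit_kind))
  invisible(x)
}

#' Run the calibration chain on one simulated or measured pull
#'
#' Applies [detect_rupture()] to every probe trace and converts accepted
#' changepoints to forces with [rupture_force()].
#'
#' @param pull A `PullRecord`.
#' @param traces Long kymograph data.frame (`probe_id`, `frame_time_s`,
#'   `intensity`).
#' @param threshold_fraction Passed to [detect_rupture()].
#' @return Data.frame of rupture events: `probe_id`, `rupture_time`,
#'   `rupture_force`, `censored`.
#' @export
calibrate_pulls <- function(pull, traces, threshold_fraction = 0.5) {
  stopifnot(inherits(pull, "PullRecord"), is.data.frame(traces))
  ids <- unique(traces$probe_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[traces$probe_id == id, ]
    det <- detect_rupture(tr, threshold_fraction)
    if (det$censored) {
      data.frame(probe_id = id, rupture_time = NA_real_,
                 rupture_force = NA_real_, censored = TRUE)
    } else {
      data.frame(probe_id = id, rupture_time = det$rupture_time,
                 rupture_force = rupture_force(pull, det$rupture_time),
                 censored = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Bell-Evans fit of mean rupture force versus loading rate
#'
#' Least-squares fit of the most-probable-force relation
#' \deqn{F^*(r) = \frac{k_B T}{x^\ddagger}
#'       \ln\!\frac{r\, x^\ddagger}{k_0 k_B T}}
#' which is linear in ln(r): the slope gives the distance to the transition
#' state, the intercept the intrinsic off rate. A non-positive slope (no
#' increase of force with loading rate) is flagged degenerate with
#' `x_dagger = Inf`.
#'
#' @param mean_forces Mean rupture forces, pN (one per loading rate), or a
#'   list of `ForceDistributionFit` objects.
#' @param loading_rates Loading rates, pN/s (> 0; at least 3 distinct).
#' @param kBT Thermal energy, pN nm.
#' @return List with `k0` (1/s), `x_dagger` (nm), `slope` (pN per e-fold),
#'   `residuals` (pN), `degenerate` (logical).
#' @export
fit_bell_evans <- function(mean_forces, loading_rates, kBT = 4.114) {
  if (is.list(mean_forces) && !is.data.frame(mean_forces)) {
    mean_forces <- vapply(mean_forces, function(f) f$mean, numeric(1))
  }
  if (length(unique(loading_rates)) < 3L) {
    stop("at least 3 distinct loading rates are required", call. = FALSE)
  }
  if (any(loading_rates <= 0)) stop("loading rates must be > 0", call. = FALSE)
  if (length(mean_forces) != length(loading_rates)) {
    stop("mean_forces and loading_rates must have equal length", call. = FALSE)
  }
  fit <- stats::lm(mean_forces ~ log(loading_rates))
  s <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  if (s <= 0) {
    return(list(k0 = NA_real_, x_dagger = Inf, slope = s,
                residuals = stats::residuals(fit), degenerate = TRUE))
  }
  x_dagger <- kBT / s
  k0 <- x_dagger / (kBT * exp(a / s))
  list(k0 = k0, x_dagger = x_dagger, slope = s,
       residuals = unname(stats::residuals(fit)), degenerate = FALSE)
}
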