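test_that("a stationary spot over 5 frames gives one track, lifetime 5 dt", {
  sp <- data.frame(frame = 0:4, x = 10 + rnorm(5, 0, 0.05),
                   y = 12 + rnorm(5, 0, 0.05), intensity = 1000)
  tr <- link_tracks(sp, max_disp = 2, max_gap = 1, frame_interval = 2,
                    n_frames = 10)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$t_on, 0)
  expect_equal(tr$t_off, 10)   # (4 + 1) * 2
  expect_false(tr$open)
})

test_that("spots separated beyond max_disp form separate tracks", {
  sp <- rbind(data.frame(frame = 0:4, x = 10, y = 10, intensity = 1),
              data.frame(frame = 0:4, x = 10 + 6 * (0:4), y = 40,
                         intensity = 1))
  tr <- link_tracks(sp, max_disp = 2, max_gap = 0, frame_interval = 1,
                    n_frames = 10)
  expect_equal(nrow(tr), 1L + 5L)  # stationary + one per jump
})

test_that("gap closing bridges a missed frame", {
  sp <- data.frame(frame = c(0, 1, 3, 4), x = 20, y = 20, intensity = 1)
  tr1 <- link_tracks(sp, max_disp = 2, max_gap = 1, frame_interval = 1,
                     n_frames = 6)
  expect_equal(nrow(tr1), 1L)
  tr0 <- link_tracks(sp, max_disp = 2, max_gap = 0, frame_interval = 1,
                     n_frames = 6)
  expect_equal(nrow(tr0), 2L)
})

test_that("a spot present in the final frame is an open (censored) track", {
  sp <- data.frame(frame = 8:9, x = 5, y = 5, intensity = 1)
  tr <- link_tracks(sp, max_disp = 2, max_gap = 1, frame_interval = 1,
                    n_frames = 10)
  expect_true(tr$open)
})

test_that("censored-exponential MLE equals its closed form on any input", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    dur <- round(rexp(n, 1 / 8), 1) + 0.1
    open <- runif(n) < 0.3
    if (sum(!open) < 10) open[1:10] <- FALSE
    tracks <- data.frame(t_on = 0, t_off = dur, open = open)
    f <- fit_lifetime(tracks, 1, n_boot = 10)
    expect_equal(f$decay_time, oracle_censored_exp_mle(dur, open),
                 tolerance = 1e-12)
  }
  # no censoring: MLE is the sample mean
  tracks <- data.frame(t_on = 0, t_off = rep(c(2, 4, 6), 4), open = FALSE)
  expect_equal(fit_lifetime(tracks, 1, n_boot = 10)$decay_time, 4)
})

test_that("lifetime recovery at a coarse stride via the cumulative fit", {
  lt <- simulate_lifetimes(9.0, 10, 300, seed = 1)
  f <- fit_lifetime(lt, 10, method = "cumulative_lsq")
  expect_lt(abs(f$decay_time - 9.0), 1.5)
  expect_true(f$ci90[1] <= f$decay_time && f$decay_time <= f$ci90[2])
})

test_that("all-open or too-few-closed inputs are errors", {
  tracks <- data.frame(t_on = 0, t_off = rexp(20, 1 / 5), open = TRUE)
  expect_error(fit_lifetime(tracks, 1), "closed tracks")
})
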