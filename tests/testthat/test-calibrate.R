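test_that("changepoint detector equals the exhaustive oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:80, 1)
    cp <- sample(5:(n - 4), 1)
    y <- c(rnorm(cp - 1, 10, 1), rnorm(n - cp + 1, 0, 1))
    det <- detect_rupture(y, threshold_fraction = 0.5)
    expect_false(det$censored)
    expect_identical(det$index, oracle_changepoint(y))
  }
})

test_that("noiseless and noisy steps are located at the right frame", {
  y <- c(rep(1000, 49), rep(0, 31))
  det <- detect_rupture(y)
  expect_identical(det$index, 50L)
  set.seed(3)
  hits <- vapply(1:25, function(i) {
    yn <- y + rnorm(80, 0, 100)  # 10 % of the step
    detect_rupture(yn)$index
  }, integer(1))
  expect_true(all(abs(hits - 50L) <= 1L))
})

test_that("flat or dropless traces are censored, not errors", {
  expect_true(detect_rupture(rep(5, 50))$censored)
  expect_true(detect_rupture(seq(100, 99, length.out = 50))$censored)
  expect_error(detect_rupture(c(1, 2, 3)), "5 frames")
})

test_that("rupture force interpolates the force channel linearly", {
  pull <- structure(list(time = c(0, 1, 2, 3), extension = c(0, 1, 2, 3),
                         force = c(10, 20, 40, 80), speed = 1,
                         temperature = 25), class = "PullRecord")
  expect_equal(rupture_force(pull, 2), 40)
  expect_equal(rupture_force(pull, 1.5), 30)  # mean of neighbors
  expect_error(rupture_force(pull, 5), "outside")
})

test_that("end-to-end calibration recovers forces within 0.5 pN of truth", {
  fe <- force_extension_model()
  rm_g <- rupture_model("gaussian_threshold", mean_force = 44, sd_force = 3.9)
  sim <- simulate_pull(fe, 100, rm_g, 40, seed = 8)
  ky <- render_kymograph(sim$pull, sim$ruptures, noise_sd = 100, seed = 9)
  ev <- calibrate_pulls(sim$pull, ky)
  ok <- !ev$censored & !sim$ruptures$censored
  expect_true(all(abs(ev$rupture_force[ok] -
                        sim$ruptures$rupture_force[ok]) < 0.5))
})

test_that("gaussian fit recovers simulated distributions; histogram agrees", {
  set.seed(12)
  ev <- data.frame(rupture_force = rnorm(96, 44, 3.9), censored = FALSE)
  fit <- fit_force_distribution(ev)
  expect_lt(abs(fit$mean - 44), 1)
  expect_lt(abs(fit$sd - 3.9), 1)
  fith <- fit_force_distribution(ev, fit_kind = "gaussian_lsq_histogram")
  expect_lt(abs(fith$mean - fit$mean), 1)
  expect_error(fit_force_distribution(c(40, 44)), "at least 10")
})

test_that("calibration round trip recovers (mean, sd) within 2 SE", {
  fe <- force_extension_model()
  ok <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    rm_g <- rupture_model("gaussian_threshold", mean_force = 44,
                          sd_force = 3.9)
    sim <- simulate_pull(fe, 100, rm_g, 40, seed = 100 + s)
    ky <- render_kymograph(sim$pull, sim$ruptures, noise_sd = 100,
                           seed = 200 + s)
    fit <- fit_force_distribution(calibrate_pulls(sim$pull, ky))
    se_mean <- 3.9 / sqrt(fit$n)
    se_sd <- 3.9 / sqrt(2 * fit$n)
    if (abs(fit$mean - 44) < 2 * se_mean && abs(fit$sd - 3.9) < 2 * se_sd) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, n_seeds - 2L)
})

test_that("Bell-Evans fit inverts its own closed form and flags degeneracy", {
  kBT <- 4.114
  k0 <- 5e-8; xd <- 1.5
  rates <- c(0.2, 0.6, 1.2, 3.7)
  means <- (kBT / xd) * log(rates * xd / (k0 * kBT))
  fit <- fit_bell_evans(means, rates)
  expect_equal(fit$x_dagger, xd, tolerance = 1e-6)
  expect_equal(fit$k0, k0, tolerance = 1e-6)
  expect_false(fit$degenerate)
  # noisy self-consistency within 20 %
  set.seed(5)
  fit2 <- fit_bell_evans(means + rnorm(4, 0, 0.1), rates)
  expect_lt(abs(fit2$x_dagger - xd) / xd, 0.2)
  expect_error(fit_bell_evans(c(40, 42), c(1, 2)), "3 distinct")
  expect_error(fit_bell_evans(c(40, 42, 44), c(-1, 1, 2)), "> 0")
  flat <- fit_bell_evans(c(44, 44, 44), rates[1:3])
  expect_true(flat$degenerate)
  expect_identical(flat$x_dagger, Inf)
})
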