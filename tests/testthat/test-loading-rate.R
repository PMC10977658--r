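test_that("colocalization matches onsets within the radius, censors the rest", {
  a <- data.frame(x = c(10, 30), y = c(10, 30), t_on = c(5, 8))
  b <- data.frame(x = c(10.5, 30), y = c(10, 25), t_on = c(20, 9))
  p <- colocalize(a, b, radius = 2, movie_end = 100)
  expect_equal(nrow(p), 2L)
  expect_equal(p$delay[1], 15)
  expect_false(p$censored[1])
  expect_true(p$censored[2])           # B is 5 px away
  expect_equal(p$censor_time[2], 92)
  expect_equal(nrow(colocalize(a[0, ], b[0, ], 2, 100)), 0L)
  # B before A cannot pair
  b2 <- data.frame(x = 10, y = 10, t_on = 2)
  p2 <- colocalize(a[1, ], b2, radius = 2, movie_end = 100)
  expect_true(p2$censored[1])
})

test_that("greedy matching prefers closer pairs, each track used once", {
  a <- data.frame(x = c(10, 11), y = c(10, 10), t_on = c(0, 0))
  b <- data.frame(x = 10.1, y = 10, t_on = 5)
  p <- colocalize(a, b, radius = 2, movie_end = 50)
  expect_false(p$censored[1])   # closer A gets the single B
  expect_true(p$censored[2])
})

test_that("site-based pairing collapses sub-diffraction duplicates", {
  # two fragmented A tracks + one B at one optical site: one pair, using
  # the earliest A onset
  a <- data.frame(x = c(10, 10.8, 50), y = c(10, 10.2, 50),
                  t_on = c(5, 40, 12))
  b <- data.frame(x = c(10.3, 50.2), y = c(10.1, 50), t_on = c(20, 80))
  p <- colocalize_sites(a, b, radius = 2, movie_end = 100)
  expect_equal(nrow(p), 2L)
  s1 <- p[p$x < 20, ]
  expect_equal(s1$t_on_A, 5)
  expect_equal(s1$delay, 15)
  s2 <- p[p$x > 20, ]
  expect_equal(s2$delay, 68)
  # a site with B only before A is censored, not mispaired
  a2 <- data.frame(x = 10, y = 10, t_on = 50)
  b2 <- data.frame(x = 10.1, y = 10, t_on = 8)
  p2 <- colocalize_sites(a2, b2, radius = 2, movie_end = 100)
  expect_true(p2$censored)
  expect_equal(p2$censor_time, 50)
  # B-only sites are ignored; empty input gives empty pairs
  expect_equal(nrow(colocalize_sites(a2[0, ], b2, 2, 100)), 0L)
})

test_that("uncensored continuous-delay MLE equals the sample mean", {
  set.seed(31)
  d <- rexp(100, 1 / 7)
  f <- fit_delay_exponential(d, 5, quantization = "none", n_boot = 20)
  expect_equal(f$decay_time, mean(d), tolerance = 1e-9)
})

test_that("interval-censored MLE removes the quantization bias", {
  set.seed(32)
  d <- rexp(400, 1 / 13.4)
  dq <- ceiling(d / 5) * 5
  f <- fit_delay_exponential(dq, 5, quantization = "delay", n_boot = 20)
  expect_lt(abs(f$decay_time - 13.4) / 13.4, 0.12)
  # naive mean of quantized delays is biased high by ~dt/2
  expect_gt(mean(dq) - f$decay_time, 1.5)
})

test_that("onset-difference quantization uses the triangular likelihood", {
  set.seed(33)
  n <- 2000
  tA <- runif(n, 0, 1e4)
  d <- rexp(n, 1 / 4.89)
  dt <- 2.5
  dobs <- (ceiling((tA + d) / dt) - ceiling(tA / dt)) * dt
  f_tri <- fit_delay_exponential(dobs, dt, quantization = "onsets",
                                 n_boot = 20)
  expect_lt(abs(f_tri$decay_time - 4.89) / 4.89, 0.06)
  # the single-interval convention would be biased low by ~dt/2 here
  f_wrong <- fit_delay_exponential(dobs, dt, quantization = "delay",
                                   n_boot = 20)
  expect_lt(f_wrong$decay_time, f_tri$decay_time - 0.7)
})

test_that("right censoring is handled where the naive mean is biased", {
  set.seed(34)
  tau <- 10
  d <- rexp(300, 1 / tau)
  cens_at <- 8
  obs <- pmin(d, cens_at)
  is_c <- d > cens_at
  pairs <- data.frame(delay = ifelse(is_c, NA, obs), censored = is_c,
                      censor_time = ifelse(is_c, cens_at, NA))
  f <- fit_delay_exponential(pairs, 5, quantization = "none", n_boot = 50)
  se <- tau / sqrt(sum(!is_c))
  expect_lt(abs(f$decay_time - tau), 2 * se)
  expect_lt(mean(obs[!is_c]), tau - 2 * se)  # naive estimate biased low
})

test_that("histogram fit agrees with the MLE on large uncensored samples", {
  set.seed(35)
  d <- ceiling(rexp(500, 1 / 13.4) / 5) * 5
  f_mle <- fit_delay_exponential(d, 5, method = "mle_censored",
                                 quantization = "delay", n_boot = 20)
  f_hist <- fit_delay_exponential(d, 5, method = "histogram_lsq",
                                  quantization = "delay", n_boot = 20)
  expect_lt(abs(f_hist$decay_time - f_mle$decay_time) / f_mle$decay_time,
            0.1)
})

test_that("rate estimate is stable under halving of the frame interval", {
  set.seed(36)
  n <- 1500
  tA <- runif(n, 0, 1e4)
  d <- rexp(n, 1 / 13.4)
  taus <- vapply(c(5, 2.5), function(dt) {
    dobs <- (ceiling((tA + d) / dt) - ceiling(tA / dt)) * dt
    fit_delay_exponential(dobs, dt, quantization = "onsets",
                          n_boot = 20)$decay_time
  }, numeric(1))
  expect_lt(abs(taus[1] - taus[2]) / taus[2], 0.05)
})

test_that("loading-rate conversion reproduces the worked arithmetic", {
  fit <- structure(list(decay_time = 13.4, ci90 = c(10, 20), n = 100,
                        n_censored = 0, method = "mle_censored"),
                   class = "ExponentialFit")
  est <- compute_loading_rate(13.2, fit)
  expect_identical(round(est$rate, 2), 0.99)
  expect_equal(est$ci90, c(13.2 / 20, 13.2 / 10))
  fit2 <- fit; fit2$decay_time <- 13.2 / 2.7
  expect_equal(compute_loading_rate(13.2, fit2)$rate, 2.7)
  expect_error(compute_loading_rate(-1, fit), "delta_F")
})

test_that("chance pairing probability follows the closed form", {
  expect_equal(chance_pairing_rate(0.006, 0, 100), 0)
  expect_equal(chance_pairing_rate(0.006, 0.001, 1), 6e-6,
               tolerance = 1e-10)
  expect_gt(chance_pairing_rate(0.006, 0.001, 1e7), 0.999)
  expect_error(chance_pairing_rate(1.5, 0.1, 10), "labeled_fraction")
})

test_that("insufficient pairs raise an informative error", {
  expect_error(fit_delay_exponential(c(1, 2, 3), 1), "at least 20")
})
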