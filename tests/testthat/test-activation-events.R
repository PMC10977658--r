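test_that("delays are exponential with the preset decay time", {
  cfg <- make_scenario("u2os_basal",
                       overrides = list(n_events = 1000,
                                        movie_duration = 1e5))
  ev <- simulate_activation_events(cfg, seed = 1)
  d <- ev$delay_s[!ev$censored]
  expect_lt(abs(mean(d) - 13.4) / 13.4, 0.1)
})

test_that("exponential generators pass a KS check on most seeds", {
  cfg <- make_scenario("u2os_basal",
                       overrides = list(n_events = 10000,
                                        movie_duration = 1e6))
  pass <- 0L
  for (s in 1:10) {
    ev <- simulate_activation_events(cfg, seed = s)
    p <- suppressWarnings(
      stats::ks.test(ev$delay_s, "pexp", rate = 1 / 13.4)$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 9L)
})

test_that("censoring bookkeeping and limits", {
  cfg <- make_scenario("u2os_basal", overrides = list(n_events = 200))
  ev <- simulate_activation_events(cfg, seed = 2)
  expect_equal(sum(ev$censored) + sum(!ev$censored), 200L)
  expect_true(all(is.na(ev$t_on_B_s[ev$censored])))
  expect_true(all(ev$t_on_B_s[!ev$censored] >= ev$t_on_A_s[!ev$censored]))

  # vanishing decay time: all delays at the numerical floor
  cfg0 <- make_scenario("u2os_basal",
                        overrides = list(delay_decay_time = 1e-12,
                                         n_events = 100))
  ev0 <- simulate_activation_events(cfg0, seed = 3)
  expect_true(all(ev0$delay_s < 1e-9))

  # decay time far beyond the movie: essentially everything censored
  cfgc <- make_scenario("u2os_basal",
                        overrides = list(delay_decay_time = 3e5,
                                         n_events = 50))
  evc <- simulate_activation_events(cfgc, seed = 4)
  expect_true(all(evc$censored))

  # positions respect the 5 sigma border margin
  m <- 5 * cfg$psf_sigma
  expect_true(all(ev$x_px >= m & ev$x_px <= cfg$field_width_px - 1 - m))
  expect_true(all(ev$y_px >= m & ev$y_px <= cfg$field_height_px - 1 - m))
})

test_that("lifetime generator quantizes and censors correctly", {
  lt <- simulate_lifetimes(9, 10, 300, seed = 1)
  expect_equal(nrow(lt), 300L)
  dur <- lt$t_off - lt$t_on
  closed <- !lt$open
  expect_true(all(dur[closed] %% 10 == 0))
  expect_true(all(dur[closed] >= 10))
  expect_true(all(lt$t_off >= lt$t_on))
  expect_equal(nrow(simulate_lifetimes(9, 10, 0, seed = 1)), 0L)
  # fine sampling limit (and no censoring): fitted decay -> sample mean
  lt_fine <- simulate_lifetimes(9, 0.001, 200, seed = 2, duration = 1e5)
  f <- fit_lifetime(lt_fine, 0.001, n_boot = 20)
  expect_equal(f$decay_time,
               sum(lt_fine$t_off - lt_fine$t_on) / sum(!lt_fine$open),
               tolerance = 1e-12)
  expect_lt(abs(f$decay_time - mean(lt_fine$true_lifetime)) /
              f$decay_time, 0.005)
})
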