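test_that("background-only movies have the configured mean", {
  cfg <- small_scenario(n_events = 0, duration = 10)
  ev <- simulate_activation_events(cfg, n_events = 0, seed = 1)
  mv <- render_movie(ev, cfg, seed = 2)
  expect_equal(mean(mv$pixels), cfg$background_mean, tolerance = 0.02)
  mv0 <- render_movie(ev, cfg, noise = FALSE)
  expect_true(all(mv0$pixels == cfg$background_mean))
})

test_that("a rendered spot integrates to the unit intensity", {
  cfg <- small_scenario(n_events = 1, duration = 10)
  ev <- simulate_activation_events(cfg, n_events = 1, seed = 3)
  ev$t_on_A_s <- 0
  mv <- render_movie(ev, cfg, noise = FALSE)
  fr <- mv$pixels[1, 1, , ] - cfg$background_mean
  cx <- round(ev$x_px) + 1L; cy <- round(ev$y_px) + 1L
  h <- ceiling(5 * cfg$psf_sigma)
  integrated <- sum(fr[cy + (-h:h), cx + (-h:h)])
  expect_lt(abs(integrated - cfg$unit_intensity) / cfg$unit_intensity, 1e-3)
  # before onset: nothing
  evB <- ev; evB$t_on_A_s <- 6
  mvB <- render_movie(evB, cfg, noise = FALSE)
  expect_true(all(mvB$pixels[1, 1, , ] == cfg$background_mean))
  expect_gt(max(mvB$pixels[4, 1, , ]), cfg$background_mean)
})

test_that("overlapping events sum instead of being dropped", {
  cfg <- small_scenario(n_events = 2, duration = 10)
  ev <- simulate_activation_events(cfg, n_events = 2, seed = 4)
  ev$x_px <- c(60, 60.4); ev$y_px <- c(60, 60.2)
  ev$t_on_A_s <- c(0, 0)
  mv <- render_movie(ev, cfg, noise = FALSE)
  fr <- mv$pixels[1, 1, , ] - cfg$background_mean
  expect_equal(sum(fr), 2 * cfg$unit_intensity, tolerance = 0.01)
})

test_that("detection recall >= 90 % and FDR <= 5 % on sparse fixtures", {
  cfg <- make_scenario("thp1_basal", seed = 1,
                       overrides = list(n_events = 20, movie_duration = 10,
                                        field_width_px = 288,
                                        field_height_px = 288))
  ev <- simulate_activation_events(cfg, seed = 5)
  ev$t_on_A_s <- 0
  mv <- render_movie(ev, cfg, seed = 6)
  sp <- detect_spots(mv$pixels[4, 1, , ])
  m <- match_positions(sp$x, sp$y, ev$x_px, ev$y_px)
  expect_gte(m$recall_hits / nrow(ev), 0.9)
  expect_lte(m$false_pos / max(nrow(sp), 1L), 0.05)
  # positions and intensities are accurate for isolated spots
  expect_lt(abs(mean(sp$intensity) - cfg$unit_intensity) /
              cfg$unit_intensity, 0.05)
})

test_that("full round trip recovers >= 90 % of uncensored events", {
  cfg <- small_scenario(n_events = 25, duration = 100, seed = 7)
  sim <- simulate_scenario(cfg, seed = 7)
  res <- analyze_loading_rate_movie(sim$movie, delta_F = cfg$delta_F,
                                    n_boot = 50, seed = 1)
  truth_unc <- sim$truth[!sim$truth$censored, ]
  found <- vapply(seq_len(nrow(truth_unc)), function(i) {
    ok <- !res$pairs$censored &
      sqrt((res$pairs$x - truth_unc$x_px[i])^2 +
             (res$pairs$y - truth_unc$y_px[i])^2) < 2
    any(ok)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})
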