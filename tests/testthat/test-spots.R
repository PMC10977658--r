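test_that("blank and flat frames yield no spots", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64))), 0L)
  expect_equal(nrow(detect_spots(matrix(7, 64, 64))), 0L)
})

test_that("two spots 10 px apart are resolved as two", {
  cfg <- small_scenario(n_events = 2, duration = 10)
  ev <- simulate_activation_events(cfg, n_events = 2, seed = 1)
  ev$x_px <- c(50, 60); ev$y_px <- c(50, 50)
  ev$t_on_A_s <- 0
  mv <- render_movie(ev, cfg, seed = 2)
  sp <- detect_spots(mv$pixels[1, 1, , ])
  expect_equal(nrow(sp), 2L)
  m <- match_positions(sp$x, sp$y, ev$x_px, ev$y_px, tol = 0.5)
  expect_equal(m$recall_hits, 2L)
})

test_that("single-spot localization is subpixel and photometry accurate", {
  cfg <- small_scenario(n_events = 1, duration = 10)
  ev <- simulate_activation_events(cfg, n_events = 1, seed = 3)
  ev$t_on_A_s <- 0
  mv <- render_movie(ev, cfg, seed = 4)
  sp <- detect_spots(mv$pixels[1, 1, , ], min_snr = 7)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$x - ev$x_px)^2 + (sp$y - ev$y_px)^2), 0.5)
  # shot noise on one aperture is ~7 %; a single spot can fluctuate 3 sigma
  expect_lt(abs(sp$intensity - cfg$unit_intensity) / cfg$unit_intensity,
            0.2)
})

test_that("unit-intensity calibration is robust to multi-molecule spots", {
  set.seed(11)
  ints <- c(rnorm(400, 1000, 100), rnorm(100, 2000, 140))
  u <- estimate_unit_intensity(ints)
  expect_lt(abs(u$unit_intensity - 1000) / 1000, 0.1)
  expect_equal(u$n_spots, 500L)
  expect_error(estimate_unit_intensity(rnorm(5, 1000, 10)), "20 spots")
})

test_that("molecule counting is exactly linear in the unit", {
  calib <- structure(list(channel = "A", unit_intensity = 1000,
                          uncertainty = 50, n_spots = 100),
                     class = "IntensityCalibration")
  expect_identical(count_molecules(0, calib), 0L)
  k <- 1:50
  expect_identical(count_molecules(k * 1000, calib), as.integer(k))
  expect_warning(cnt <- count_molecules(-5, calib), "clamped")
  expect_identical(cnt, 0L)
})

test_that("delta stack conserves signal before clamping and clamps after", {
  cfg <- small_scenario(n_events = 3, duration = 20)
  sim <- simulate_scenario(cfg, seed = 5)
  d_raw <- delta_stack(sim$movie, 1, clamp = FALSE)
  total <- apply(d_raw$pixels[, 1, , ], c(2, 3), sum)
  last <- sim$movie$pixels[dim(sim$movie$pixels)[1], 1, , ]
  expect_equal(total, last - sim$movie$pixels[1, 1, , ], tolerance = 1e-12)
  d <- delta_stack(sim$movie, 1)
  expect_true(all(d$pixels >= 0))
  # static movie: all-zero increments
  stat <- movie_stack(array(5, dim = c(3, 1, 8, 8)), 100, 1, "A")
  expect_true(all(delta_stack(stat, 1)$pixels == 0))
  expect_error(delta_stack(movie_stack(array(1, dim = c(1, 1, 8, 8)),
                                       100, 1, "A")), "2 frames")
})

test_that("one activation produces a single positive blob at its frame", {
  cfg <- small_scenario(n_events = 1, duration = 20)
  ev <- simulate_activation_events(cfg, n_events = 1, seed = 6)
  ev$t_on_A_s <- 7.4   # frame 3 is the first >= t_on (stride 2.5)
  mv <- render_movie(ev, cfg, noise = FALSE)
  d <- delta_stack(mv, 1)
  per_frame <- apply(d$pixels[, 1, , ], 1, sum)
  expect_gt(per_frame[3], 0.99 * cfg$unit_intensity)
  expect_true(all(per_frame[-3] == 0))
})

test_that("median filtering radius 0 is the identity on increments", {
  cfg <- small_scenario(n_events = 2, duration = 10)
  sim <- simulate_scenario(cfg, seed = 7)
  a <- delta_stack(sim$movie, 1, median_radius = 0)
  b <- delta_stack(sim$movie, 1)
  expect_identical(a$pixels, b$pixels)
  # filtering kills single-pixel outliers but keeps the blob
  img <- matrix(0, 21, 21)
  img[11, 11] <- 500
  expect_equal(max(otsforce:::median_filter(img, 1)), 0)
})

test_that("region totals subtract background over the mask", {
  px <- array(0, dim = c(2, 1, 10, 10))
  px[1, 1, , ] <- 3
  px[1, 1, 3:5, 3:5] <- 13
  mv <- movie_stack(px, 100, 1, "A")
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_equal(region_total(mv, mask, frame = 0), 9 * 10)
  expect_equal(region_total(mv, mask, frame = 1), 0)
  one <- matrix(FALSE, 10, 10); one[4, 4] <- TRUE
  expect_equal(region_total(mv, one, frame = 0, background = 3), 10)
  expect_warning(z <- region_total(mv, matrix(FALSE, 10, 10), frame = 0),
                 "empty mask")
  expect_equal(z, 0)
  # refresh simulation: quencher erasure resets signal
  expect_lt(abs(region_total(mv, mask, frame = 1)),
            0.1 * region_total(mv, mask, frame = 0))
})

test_that("trace alignment centers a shifted pulse at lag zero", {
  n_t <- 41
  pulse <- exp(-((1:n_t) - 21)^2 / 8)
  set.seed(13)
  shifts <- sample(-8:8, 100, replace = TRUE)
  traces <- t(vapply(shifts, function(s) {
    out <- rep(0, n_t)
    src <- (1:n_t) - s
    ok <- src >= 1 & src <= n_t
    out[ok] <- pulse[src[ok]]
    out + rnorm(n_t, 0, 0.01)
  }, numeric(n_t)))
  al <- align_traces_to_peak(traces, traces)
  expect_equal(al$mean[al$lag == 0], max(al$mean), tolerance = 1e-9)
  peak_region <- al$mean[abs(al$lag) <= 2]
  expect_equal(peak_region[3], 1, tolerance = 0.05)
  # single trace aligned to itself peaks at lag 0
  one <- matrix(pulse, 1)
  a1 <- align_traces_to_peak(one, one)
  expect_equal(a1$lag[which.max(a1$mean)], 0L)
  # flat reference excluded, ties flagged
  ref <- rbind(pulse, rep(1, n_t), c(rep(0, 10), 1, rep(0, 19), 1,
                                     rep(0, 10)))
  tr3 <- rbind(pulse, pulse, pulse)
  a3 <- align_traces_to_peak(tr3, ref)
  expect_equal(attr(a3, "n_excluded_flat"), 1L)
  expect_equal(attr(a3, "n_ties"), 1L)
})
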