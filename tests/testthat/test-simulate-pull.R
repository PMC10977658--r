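fe <- force_extension_model()

test_that("pull records are monotone ramps and reject bad speeds", {
  rm_g <- rupture_model("gaussian_threshold", mean_force = 44, sd_force = 3.9)
  expect_error(simulate_pull(fe, 0, rm_g, 5), "speed")
  expect_error(simulate_pull(fe, -10, rm_g, 5), "speed")
  sim <- simulate_pull(fe, 100, rm_g, 5, seed = 1)
  expect_true(all(diff(sim$pull$force) >= 0))
  expect_true(all(diff(sim$pull$time) > 0))
  expect_equal(length(sim$pull$time), length(sim$pull$force))
})

test_that("gaussian_threshold ruptures reproduce the generative mean", {
  rm_g <- rupture_model("gaussian_threshold", mean_force = 44, sd_force = 3.9)
  sim <- simulate_pull(fe, 100, rm_g, 96, seed = 11)
  f <- sim$ruptures$rupture_force[!sim$ruptures$censored]
  expect_lt(abs(mean(f) - 44), 1)
  # the drawn forces must sit on the ramp: interpolated force at the
  # rupture time equals the drawn rupture force
  idx <- which(!sim$ruptures$censored)[1:10]
  back <- rupture_force(sim$pull, sim$ruptures$rupture_time[idx])
  expect_equal(back, sim$ruptures$rupture_force[idx], tolerance = 1e-6)
})

test_that("censoring bookkeeping: every probe is accounted for", {
  # force a censored fraction by a mean near the ramp ceiling
  rm_hi <- rupture_model("gaussian_threshold", mean_force = 69, sd_force = 3)
  sim <- simulate_pull(fe, 100, rm_hi, 60, seed = 4, max_force = 70)
  expect_equal(nrow(sim$ruptures), 60L)
  expect_gt(sum(sim$ruptures$censored), 0)
  expect_true(all(is.na(sim$ruptures$rupture_force[sim$ruptures$censored])))
  expect_equal(sum(sim$ruptures$censored) + sum(!sim$ruptures$censored), 60L)
})

test_that("bell_evans mean rupture force increases with pulling speed", {
  means <- vapply(c(20, 50, 100, 300), function(s) {
    sim <- simulate_pull(fe, s, rupture_model("bell_evans"), 100, seed = s)
    mean(sim$ruptures$rupture_force, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("generators are bit-reproducible for a fixed seed", {
  rm_g <- rupture_model("gaussian_threshold", mean_force = 44, sd_force = 3.9)
  a <- simulate_pull(fe, 100, rm_g, 20, seed = 7)
  b <- simulate_pull(fe, 100, rm_g, 20, seed = 7)
  expect_identical(a, b)
  cfg <- small_scenario(seed = 5)
  expect_identical(simulate_activation_events(cfg),
                   simulate_activation_events(cfg))
  expect_identical(simulate_lifetimes(9, 10, 50, seed = 3),
                   simulate_lifetimes(9, 10, 50, seed = 3))
})

test_that("kymograph traces step at the rupture frame", {
  rm_g <- rupture_model("gaussian_threshold", mean_force = 44, sd_force = 3.9)
  sim <- simulate_pull(fe, 100, rm_g, 3, seed = 2)
  ky <- render_kymograph(sim$pull, sim$ruptures, noise_sd = 0)
  for (i in which(!sim$ruptures$censored)) {
    tr <- ky[ky$probe_id == sim$ruptures$probe_id[i], ]
    low <- tr$intensity == 0
    expect_equal(min(tr$frame_time_s[low]),
                 min(tr$frame_time_s[tr$frame_time_s >= sim$ruptures$rupture_time[i]]))
  }
  # censored probe: constant trace
  cen <- data.frame(probe_id = "c1", rupture_time = NA_real_,
                    rupture_force = NA_real_, censored = TRUE)
  kyc <- render_kymograph(sim$pull, cen, noise_sd = 0)
  expect_true(all(kyc$intensity == 1000))
})
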