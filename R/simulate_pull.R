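#' Probe rupture model for pull simulations
#'
#' Two mechanisms for assigning dehybridization events along a force ramp:
#' \describe{
#'   \item{gaussian_threshold}{each probe carries a rupture force drawn from
#'     N(mean_force, sd_force); it ruptures when the ramp first reaches that
#'     force. Reproduces the empirical Gaussian force distributions.}
#'   \item{bell_evans}{stochastic rupture with force-dependent hazard
#'     \eqn{k(F) = k_0 \exp(F x^\ddagger / k_B T)}; reproduces the increase
#'     of mean rupture force with loading rate.}
#' }
#'
#' Default Bell-Evans parameters (`k0` 5e-8 /s, `x_dagger` 1.5 nm) put the
#' mean rupture force near 44 pN at ~1 pN/s with a slope of
#' \eqn{k_BT/x^\ddagger \approx 2.7} pN per e-fold of loading rate.
#'
#' @param kind `"gaussian_threshold"` or `"bell_evans"`.
#' @param mean_force,sd_force Gaussian parameters, pN (sd > 0).
#' @param k0 Intrinsic off rate at zero force, 1/s (> 0).
#' @param x_dagger Distance to the transition state, nm (> 0).
#' @param kBT Thermal energy, pN nm.
#' @return An object of class `RuptureModel`.
#' @export
rupture_model <- function(kind = c("gaussian_threshold", "bell_evans"),
                          mean_force = NULL, sd_force = NULL,
                          k0 = 5e-8, x_dagger = 1.5, kBT = 4.114) {
  kind <- match.arg(kind)
  if (kind == "gaussian_threshold") {
    assert_scalar(mean_force, "mean_force", positive = TRUE)
    assert_scalar(sd_force, "sd_force", positive = TRUE)
  } else {
    assert_scalar(k0, "k0", positive = TRUE)
    assert_scalar(x_dagger, "x_dagger", positive = TRUE)
    assert_scalar(kBT, "kBT", positive = TRUE)
  }
  structure(list(kind = kind, mean_force = mean_force, sd_force = sd_force,
                 k0 = k0, x_dagger = x_dagger, kBT = kBT),
            class = "RuptureModel")
}

#' Simulate a constant-speed pull with stochastic probe rupture
#'
#' Generates a tweezers pull record: the template is extended at constant
#' speed from `start_force` until `max_force`, the tension at each time is
#' obtained by inverting the force-extension model, and each of `n_probes`
#' hybridized probes is assigned a rupture along the ramp.
#'
#' Gaussian-threshold ruptures are direct draws mapped onto the ramp;
#' Bell-Evans ruptures are first-passage samples obtained by inversion on
#' the trapezoid-integrated hazard along the actual discrete force trace,
#' which is exact given the discretization. A probe whose rupture force (or
#' survival draw) exceeds the simulated range is flagged censored, never
#' dropped.
#'
#' @param fe_model A [force_extension_model()].
#' @param speed Stretching speed, nm/s (> 0).
#' @param rupture A [rupture_model()].
#' @param n_probes Number of probes on the template.
#' @param seed Optional RNG seed.
#' @param dt Sampling interval of the record, s (also the kymograph frame
#'   interval downstream).
#' @param start_force Tension at the start of the ramp, pN (probes are
#'   hybridized at low tension before the pull).
#' @param max_force Tension at which the ramp stops, pN.
#' @param temperature Record temperature, degrees C (metadata only).
#' @return A list with elements `pull` (class `PullRecord`: `time`,
#'   `extension`, `force`, `speed`, `temperature`) and `ruptures` (a
#'   data.frame with `probe_id`, `rupture_time`, `rupture_force`,
#'   `censored`; censored rows carry NA time/force).
#' @export
simulate_pull <- function(fe_model, speed, rupture, n_probes,
                          seed = NULL, dt = 0.1, start_force = 5,
                          max_force = 70, temperature = 25) {
  stopifnot(inherits(fe_model, "ForceExtensionModel"),
            inherits(rupture, "RuptureModel"))
  assert_scalar(speed, "speed", positive = TRUE)
  assert_scalar(n_probes, "n_probes", positive = TRUE)
  assert_scalar(dt, "dt", positive = TRUE)
  assert_scalar(start_force, "start_force", nonneg = TRUE)
  assert_scalar(max_force, "max_force", positive = TRUE)
  if (max_force <= start_force) stop("max_force must exceed start_force",
                                     call. = FALSE)

  x0 <- model_extension(fe_model, start_force)
  x1 <- model_extension(fe_model, max_force)
  t_end <- (x1 - x0) / speed
  time <- seq(0, t_end, by = dt)
  if (time[length(time)] < t_end) time <- c(time, t_end)
  extension <- x0 + speed * time
  force <- model_force_fun(fe_model, f_max = max_force * 1.05)(extension)
  force <- cummax(force)  # guard against interpolation wiggle

  pull <- structure(list(time = time, extension = extension, force = force,
                         speed = speed, temperature = temperature),
                    class = "PullRecord")

  ruptures <- with_seed(seed, {
    if (rupture$kind == "gaussian_threshold") {
      f_r <- stats::rnorm(n_probes, rupture$mean_force, rupture$sd_force)
      censored <- f_r > max(force) | f_r < min(force)
      t_r <- rep(NA_real_, n_probes)
      ok <- !censored
      t_r[ok] <- stats::approx(force, time, xout = f_r[ok], ties = "ordered")$y
      data.frame(probe_id = sprintf("p%03d", seq_len(n_probes)),
                 rupture_time = t_r,
                 rupture_force = ifelse(censored, NA_real_, f_r),
                 censored = censored)
    } else {
      hazard <- rupture$k0 * exp(force * rupture$x_dagger / rupture$kBT)
      # cumulative trapezoid integral of the hazard along the ramp
      H <- c(0, cumsum((hazard[-1] + hazard[-length(hazard)]) / 2 * diff(time)))
      E <- stats::rexp(n_probes)
      censored <- E > H[length(H)]
      t_r <- rep(NA_real_, n_probes)
      ok <- !censored
      t_r[ok] <- stats::approx(H, time, xout = E[ok], ties = "ordered")$y
      f_r <- rep(NA_real_, n_probes)
      f_r[ok] <- stats::approx(time, force, xout = t_r[ok], ties = "ordered")$y
      data.frame(probe_id = sprintf("p%03d", seq_len(n_probes)),
                 rupture_time = t_r, rupture_force = f_r, censored = censored)
    }
  })
  list(pull = pull, ruptures = ruptures)
}

#' @export
print.PullRecord <- function(x, ...) {
  cat(sprintf("PullRecord: %d samples, %.3g-%.3g pN at %g nm/s (%g C)\n",
              length(x$time), min(x$force), max(x$force), x$speed,
              x$temperature))
  invisible(x)
}

#' Render per-probe kymograph intensity traces for a pull
#'
#' Each probe's fluorescence trace is `unit_intensity` photons while
#' hybridized and `background` after its rupture frame, plus Gaussian read
#' noise. Censored probes (no rupture within the ramp) give constant
#' traces.
#'
#' @param pull A `PullRecord` from [simulate_pull()].
#' @param ruptures Rupture table from [simulate_pull()] (times must lie
#'   within the pull record).
#' @param noise_sd Gaussian read-noise standard deviation, photons.
#' @param unit_intensity Hybridized-probe intensity, photons.
#' @param background Post-rupture intensity level, photons.
#' @param seed Optional RNG seed.
#' @return A long data.frame with columns `probe_id`, `frame_time_s`,
#'   `intensity` (class `KymographTraces`).
#' @export
render_kymograph <- function(pull, ruptures, noise_sd = 0,
                             unit_intensity = 1000, background = 0,
                             seed = NULL) {
  stopifnot(inherits(pull, "PullRecord"), is.data.frame(ruptures))
  assert_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  tr <- ruptures$rupture_time[!ruptures$censored]
  if (any(tr < min(pull$time) | tr > max(pull$time))) {
    stop("rupture times outside the pull record", call. = FALSE)
  }
  n_t <- length(pull$time)
  out <- with_seed(seed, {
    traces <- lapply(seq_len(nrow(ruptures)), function(i) {
      if (ruptures$censored[i]) {
        base <- rep(unit_intensity, n_t)
      } else {
        base <- ifelse(pull$time < ruptures$rupture_time[i],
                       unit_intensity, background)
      }
      if (noise_sd > 0) base <- base + stats::rnorm(n_t, 0, noise_sd)
      data.frame(probe_id = ruptures$probe_id[i],
                 frame_time_s = pull$time, intensity = base)
    })
    do.call(rbind, traces)
  })
  class(out) <- c("KymographTraces", class(out))
  out
}
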