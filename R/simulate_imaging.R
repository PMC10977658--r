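#' Simulate serial-sensor activation events
#'
#' Generates ground-truth two-channel activation events for a scenario:
#' event positions are uniform over the field (kept `5 * psf_sigma` px away
#' from the borders to avoid truncated-PSF bias in recovery tests), the
#' low-threshold channel-A onset is uniform over the movie, and the
#' channel-B onset follows after an exponential delay with the scenario's
#' decay time. Events whose B onset falls beyond the movie end are
#' right-censored (`t_on_B_s` is NA).
#'
#' Delays are generated continuously; quantization to the acquisition
#' stride happens at observation time (rendering / detection), matching
#' stroboscopic imaging (short exposure every `frame_interval`).
#'
#' @param cfg A `ScenarioConfig`.
#' @param n_events Number of events (default: the scenario's `n_events`).
#' @param seed RNG seed (default: the scenario's stored seed).
#' @return Data.frame of class `ActivationTruth`: `event_id`, `x_px`,
#'   `y_px`, `t_on_A_s`, `t_on_B_s` (NA when censored), `delay_s` (true
#'   continuous delay), `censored`.
#' @export
simulate_activation_events <- function(cfg, n_events = cfg$n_events,
                                       seed = cfg$seed) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  if (is.na(seed)) seed <- NULL
  n <- as.integer(n_events)
  margin <- 5 * cfg$psf_sigma
  if (cfg$field_width_px <= 2 * margin || cfg$field_height_px <= 2 * margin) {
    stop("field too small for the 5 sigma border margin", call. = FALSE)
  }
  out <- with_seed(seed, {
    x <- stats::runif(n, margin, cfg$field_width_px - 1 - margin)
    y <- stats::runif(n, margin, cfg$field_height_px - 1 - margin)
    t_a <- stats::runif(n, 0, cfg$movie_duration)
    delay <- stats::rexp(n, rate = 1 / cfg$delay_decay_time)
    t_b <- t_a + delay
    censored <- t_b > cfg$movie_duration
    data.frame(event_id = seq_len(n), x_px = x, y_px = y, t_on_A_s = t_a,
               t_on_B_s = ifelse(censored, NA_real_, t_b),
               delay_s = delay, censored = censored)
  })
  class(out) <- c("ActivationTruth", class(out))
  attr(out, "scenario") <- cfg$name
  out
}

# Pixel-integrated 2-D Gaussian patch of total intensity `total` centered at
# (x, y) (0-based pixel-center coordinates), over pixel columns xs and rows
# ys. Returns matrix [ys, xs].
psf_patch <- function(x, y, sigma, total, xs, ys) {
  px <- stats::pnorm(xs + 0.5, x, sigma) - stats::pnorm(xs - 0.5, x, sigma)
  py <- stats::pnorm(ys + 0.5, y, sigma) - stats::pnorm(ys - 0.5, y, sigma)
  total * outer(py, px)
}

#' Render a two-channel activation movie
#'
#' Builds a `T x C x Y x X` photon-count stack from ground-truth events:
#' each active sensor contributes a pixel-integrated 2-D Gaussian of total
#' `unit_intensity` photons centered at its position from its onset frame
#' onward (channel 1 = low-threshold sensor A, channel 2 = high-threshold
#' sensor B); overlapping events sum. Poisson shot noise is applied to
#' signal plus uniform background. Frame `k` (0-based) samples the field at
#' time `k * frame_interval`; a sensor is visible in frame `k` when its
#' onset time is `<= k * frame_interval`.
#'
#' @param truth Events from [simulate_activation_events()].
#' @param cfg The `ScenarioConfig` used to generate them.
#' @param seed RNG seed for the shot noise.
#' @param noise If `FALSE`, return the noise-free expected photon counts.
#' @return A `MovieStack`: list with `pixels` (T x C x Y x X array),
#'   `pixel_size` (nm), `frame_interval` (s), `channel_names`.
#' @export
render_movie <- function(truth, cfg, seed = cfg$seed, noise = TRUE) {
  stopifnot(is.data.frame(truth), inherits(cfg, "ScenarioConfig"))
  if (is.na(seed)) seed <- NULL
  W <- as.integer(cfg$field_width_px)
  H <- as.integer(cfg$field_height_px)
  if (nrow(truth) > 0 &&
      (any(truth$x_px < 0 | truth$x_px > W - 1) ||
       any(truth$y_px < 0 | truth$y_px > H - 1))) {
    stop("event positions outside the field", call. = FALSE)
  }
  dt <- cfg$frame_interval
  n_frames <- floor(cfg$movie_duration / dt) + 1L
  frame_times <- (seq_len(n_frames) - 1L) * dt
  half <- ceiling(5 * cfg$psf_sigma)

  # precompute each event's PSF patch and bounding box
  patches <- lapply(seq_len(nrow(truth)), function(i) {
    x <- truth$x_px[i]; y <- truth$y_px[i]
    xs <- max(0L, floor(x) - half):min(W - 1L, floor(x) + half)
    ys <- max(0L, floor(y) - half):min(H - 1L, floor(y) + half)
    list(xs = xs + 1L, ys = ys + 1L,
         patch = psf_patch(x, y, cfg$psf_sigma, cfg$unit_intensity, xs, ys))
  })

  onsets <- list(truth$t_on_A_s, truth$t_on_B_s)
  pixels <- array(0, dim = c(n_frames, 2L, H, W))
  for (ch in 1:2) {
    signal <- matrix(cfg$background_mean, H, W)
    ord <- order(onsets[[ch]], na.last = TRUE)
    next_i <- 1L
    for (k in seq_len(n_frames)) {
      while (next_i <= length(ord)) {
        i <- ord[next_i]
        t_on <- onsets[[ch]][i]
        if (is.na(t_on) || t_on > frame_times[k]) break
        p <- patches[[i]]
        signal[p$ys, p$xs] <- signal[p$ys, p$xs] + p$patch
        next_i <- next_i + 1L
      }
      pixels[k, ch, , ] <- signal
    }
  }
  if (noise) {
    pixels <- with_seed(seed, {
      array(as.double(stats::rpois(length(pixels), lambda = pixels)),
            dim = dim(pixels))
    })
  }
  movie_stack(pixels, pixel_size = cfg$pixel_size, frame_interval = dt,
              channel_names = c("A", "B"))
}

#' Construct a MovieStack container
#'
#' @param pixels T x C x Y x X numeric array.
#' @param pixel_size Pixel size, nm.
#' @param frame_interval Frame interval, s.
#' @param channel_names Character vector of length C.
#' @return An object of class `MovieStack`.
#' @export
movie_stack <- function(pixels, pixel_size, frame_interval, channel_names) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L)
  assert_scalar(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (length(channel_names) != dim(pixels)[2]) {
    stop("channel_names length must match the channel dimension", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_names = as.character(channel_names)),
            class = "MovieStack")
}

#' @export
print.MovieStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("MovieStack: %d frames x %d channels (%s) x %d x %d px, %g nm/px, %g s/frame\n",
              d[1], d[2], paste(x$channel_names, collapse = ","), d[3], d[4],
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Simulate stroboscopically observed spot lifetimes
#'
#' True lifetimes are exponential with the given mean; on-times are uniform
#' over `duration`. Observation quantizes: the observed on-time is the first
#' frame at or after the true on-time, and the observed duration is the
#' true lifetime rounded up to a whole number of frame intervals (every
#' spot spans at least one frame; sub-frame blinking is not modeled).
#' Tracks whose observed end would fall beyond the movie are flagged open
#' (right-censored) with `t_off` at the movie end.
#'
#' @param mean_lifetime Mean spot lifetime, s (> 0).
#' @param frame_interval Acquisition stride, s.
#' @param n Number of spots.
#' @param seed RNG seed.
#' @param duration Movie length, s; the default (50 mean lifetimes) keeps
#'   end-of-movie censoring near 2 %.
#' @return Data.frame of class `LifetimeTracks`: `track_id`, `x_px`,
#'   `y_px`, `t_on`, `t_off`, `open`, `true_lifetime`.
#' @export
simulate_lifetimes <- function(mean_lifetime, frame_interval, n, seed = NULL,
                               duration = 50 * mean_lifetime) {
  assert_scalar(mean_lifetime, "mean_lifetime", positive = TRUE)
  assert_scalar(frame_interval, "frame_interval", positive = TRUE)
  assert_scalar(n, "n", nonneg = TRUE)
  n <- as.integer(n)
  out <- with_seed(seed, {
    if (n == 0L) {
      data.frame(track_id = integer(0), x_px = numeric(0), y_px = numeric(0),
                 t_on = numeric(0), t_off = numeric(0), open = logical(0),
                 true_lifetime = numeric(0))
    } else {
      L <- stats::rexp(n, rate = 1 / mean_lifetime)
      t0 <- stats::runif(n, 0, duration)
      t_on <- ceiling(t0 / frame_interval) * frame_interval
      d_obs <- pmax(1, ceiling(L / frame_interval)) * frame_interval
      t_off <- t_on + d_obs
      open <- t_off > duration
      t_off[open] <- pmax(t_on[open],
                          floor(duration / frame_interval) * frame_interval)
      data.frame(track_id = seq_len(n),
                 x_px = stats::runif(n, 0, 100),
                 y_px = stats::runif(n, 0, 100),
                 t_on = t_on, t_off = t_off, open = open, true_lifetime = L)
    }
  })
  class(out) <- c("LifetimeTracks", class(out))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "duration") <- duration
  out
}
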