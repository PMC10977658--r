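#' Named generative scenario presets
#'
#' A `ScenarioConfig` carries every parameter needed to generate a synthetic
#' two-channel activation movie: the generative delay decay time `tau`
#' between low- and high-threshold sensor activation, the force step
#' `delta_F` between the two sensors, acquisition stride, movie length,
#' imaging parameters and field geometry.
#'
#' Presets encode the measured cell conditions:
#' \describe{
#'   \item{u2os_basal}{epithelial cells, tau 13.4 s, dF 13.2 pN, 5 s stride
#'     (rate 0.99 pN/s)}
#'   \item{u2os_blebbistatin}{actomyosin inhibition, rate 0.74 pN/s}
#'   \item{u2os_ck666}{Arp2/3 inhibition, rate 0.56 pN/s}
#'   \item{thp1_basal}{monocytes on LDVP ligand, rate 2.7 pN/s, 2.5 s stride}
#'   \item{thp1_hypertonic}{rate 1.9 pN/s}
#'   \item{thp1_hypotonic}{rate 4.0 pN/s}
#'   \item{thp1_cytochalasinD}{0.5 uM cytochalasin D, rate 1.8 pN/s}
#'   \item{fibroblast_dp30}{focal-adhesion subcluster imaging at 10 s
#'     stride; carries the 9.0 s spot lifetime instead of a delay time}
#' }
#' Where only a loading rate was reported, tau = delta_F / rate.
#'
#' Imaging defaults model a single-molecule TIRF setup: 100 nm pixels, PSF
#' sigma 1.2 px, 1000 photons per fluorophore, 100 photons/px background.
#' The field (288 x 288 px) and the number of activation events per movie
#' (180) are generator choices that keep per-frame spot density low enough
#' for diffraction-limited detection while giving enough delay pairs for a
#' stable exponential fit; see the methods vignette.
#'
#' @param name A preset name (see Details) or `"custom"`, in which case all
#'   fields must be supplied via `overrides`.
#' @param overrides Named list of field values replacing preset defaults.
#'   Unknown field names are an error.
#' @param seed Optional integer stored in the config and used as the default
#'   seed by generators consuming it.
#' @return A validated list of class `ScenarioConfig`.
#' @export
#' @examples
#' cfg <- make_scenario("u2os_basal", seed = 1)
#' cfg$delay_decay_time
#' scenario_rate(cfg)
make_scenario <- function(name, overrides = list(), seed = NULL) {
  presets <- scenario_presets()
  if (identical(name, "custom")) {
    base <- scenario_defaults()
  } else if (name %in% names(presets)) {
    base <- utils::modifyList(scenario_defaults(), presets[[name]])
  } else {
    stop(sprintf("unknown preset '%s'; known presets: %s, custom", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("'overrides' must be a fully named list", call. = FALSE)
    }
    bad <- setdiff(names(overrides), names(scenario_defaults()))
    if (length(bad)) {
      stop(sprintf("unknown scenario field(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    base <- utils::modifyList(base, overrides)
  }
  cfg <- c(list(name = name), base)
  cfg$seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  validate_scenario(cfg)
}

scenario_defaults <- function() {
  list(
    delay_decay_time = NA_real_,   # s, generative tau of channel-B delay
    delta_F = NA_real_,            # pN, force step between the two sensors
    frame_interval = NA_real_,     # s, acquisition stride
    movie_duration = NA_real_,     # s
    sensor_density = 0.7,          # labeled sensors per um^2
    labeled_fraction = 0.006,      # fraction of all surface sensors labeled
    unit_intensity = 1000,         # photons per fluorophore
    background_mean = 100,         # photons per pixel
    psf_sigma = 1.2,               # px
    pixel_size = 100,              # nm
    field_width_px = 288,
    field_height_px = 288,
    n_events = 180,                # activation events per movie
    lifetime_mean = NA_real_,      # s, spot lifetime (refreshing scenarios)
    seed = NA_integer_
  )
}

#' @rdname make_scenario
#' @export
scenario_presets <- function() {
  dF <- 13.2
  list(
    u2os_basal = list(delay_decay_time = 13.4, delta_F = dF,
                      frame_interval = 5, movie_duration = 300),
    u2os_blebbistatin = list(delay_decay_time = dF / 0.74, delta_F = dF,
                             frame_interval = 5, movie_duration = 300),
    u2os_ck666 = list(delay_decay_time = dF / 0.56, delta_F = dF,
                      frame_interval = 5, movie_duration = 300),
    thp1_basal = list(delay_decay_time = dF / 2.7, delta_F = dF,
                      frame_interval = 2.5, movie_duration = 250),
    thp1_hypertonic = list(delay_decay_time = dF / 1.9, delta_F = dF,
                           frame_interval = 2.5, movie_duration = 250),
    thp1_hypotonic = list(delay_decay_time = dF / 4.0, delta_F = dF,
                          frame_interval = 2.5, movie_duration = 250),
    thp1_cytochalasinD = list(delay_decay_time = dF / 1.8, delta_F = dF,
                              frame_interval = 2.5, movie_duration = 250),
    fibroblast_dp30 = list(delay_decay_time = 13.4, delta_F = dF,
                           frame_interval = 10, movie_duration = 450,
                           lifetime_mean = 9.0)
  )
}

validate_scenario <- function(cfg) {
  req <- c("delay_decay_time", "delta_F", "frame_interval", "movie_duration")
  for (f in req) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]])) {
      stop(sprintf("scenario field '%s' is missing or not a number", f),
           call. = FALSE)
    }
  }
  assert_scalar(cfg$delay_decay_time, "delay_decay_time", positive = TRUE)
  assert_scalar(cfg$delta_F, "delta_F", positive = TRUE)
  assert_scalar(cfg$frame_interval, "frame_interval", positive = TRUE)
  assert_scalar(cfg$movie_duration, "movie_duration", positive = TRUE)
  assert_fraction(cfg$labeled_fraction, "labeled_fraction")
  assert_scalar(cfg$sensor_density, "sensor_density", positive = TRUE)
  assert_scalar(cfg$unit_intensity, "unit_intensity", positive = TRUE)
  assert_scalar(cfg$background_mean, "background_mean", nonneg = TRUE)
  assert_scalar(cfg$psf_sigma, "psf_sigma", positive = TRUE)
  assert_scalar(cfg$pixel_size, "pixel_size", positive = TRUE)
  assert_scalar(cfg$field_width_px, "field_width_px", positive = TRUE)
  assert_scalar(cfg$field_height_px, "field_height_px", positive = TRUE)
  assert_scalar(cfg$n_events, "n_events", nonneg = TRUE)
  structure(cfg, class = "ScenarioConfig")
}

#' Generative loading rate of a scenario
#'
#' The rate the analysis chain is expected to recover: `delta_F` divided by
#' the generative delay decay time.
#'
#' @param cfg A `ScenarioConfig`.
#' @return Loading rate in pN/s.
#' @export
scenario_rate <- function(cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  cfg$delta_F / cfg$delay_decay_time
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat(sprintf("Scenario '%s': tau = %.3g s, dF = %.3g pN (rate %.3g pN/s)\n",
              x$name, x$delay_decay_time, x$delta_F, scenario_rate(x)))
  cat(sprintf("  stride %g s, duration %g s, field %d x %d px (%g nm px), %d events\n",
              x$frame_interval, x$movie_duration, x$field_width_px,
              x$field_height_px, x$pixel_size, x$n_events))
  invisible(x)
}
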