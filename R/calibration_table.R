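#' Sensor dehybridization-force calibration table
#'
#' Per-sensor dehybridization force under a ramped load, as measured by
#' optical-tweezers stretching of probe-decorated ssDNA templates. Forces
#' depend on duplex length, GC content, backbone chemistry, temperature and
#' loading rate, so each row is keyed by (sensor, temperature, speed).
#'
#' Room-temperature rows (25 C, 100 nm/s) cover the four 18 bp probes
#' (32/35/44/55 pN for GC 39/50/61/83 %), the 15 bp probes (11 pN below the
#' corresponding 18 bp probe), the 25 bp GC-84 % probe (60 pN) and the
#' PNA-DNA hybrid (95 pN). The GC-61 % probe carries a speed series
#' (43.1/43.0/44/45.5 pN at 20/50/100/300 nm/s) used for loading-rate trend
#' checks. The 37 C rows are the cell-facing sensors dp16/dp30/dp46/dp58,
#' named by their nominal thresholds.
#'
#' `n` is the number of rupture events behind a Gaussian fit where known;
#' simulation presets reuse it as the sample size.
#'
#' @return A data.frame with columns `sensor`, `duplex_bp`, `gc`,
#'   `chemistry` ("DNA" or "PNA_DNA"), `temperature_c`, `speed_nm_s`,
#'   `force_mean_pN`, `force_sd_pN` (NA where unpublished), `n` (NA where
#'   unknown).
#' @seealso [ots_delta_F()]
#' @export
calibration_table <- function() {
  tab <- rbind(
    data.frame(sensor = "l18_gc39", duplex_bp = 18, gc = 0.39, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 32,
               force_sd_pN = NA_real_, n = 89),
    data.frame(sensor = "l18_gc50", duplex_bp = 18, gc = 0.50, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 35,
               force_sd_pN = NA_real_, n = 67),
    data.frame(sensor = "l18_gc61", duplex_bp = 18, gc = 0.61, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 20, force_mean_pN = 43.1,
               force_sd_pN = 3.3, n = 89),
    data.frame(sensor = "l18_gc61", duplex_bp = 18, gc = 0.61, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 50, force_mean_pN = 43.0,
               force_sd_pN = 2.9, n = NA_real_),
    data.frame(sensor = "l18_gc61", duplex_bp = 18, gc = 0.61, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 44,
               force_sd_pN = 3.9, n = 96),
    data.frame(sensor = "l18_gc61", duplex_bp = 18, gc = 0.61, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 300, force_mean_pN = 45.5,
               force_sd_pN = 4.0, n = 90),
    data.frame(sensor = "l18_gc83", duplex_bp = 18, gc = 0.83, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 55,
               force_sd_pN = NA_real_, n = 52),
    data.frame(sensor = "l15_gc40", duplex_bp = 15, gc = 0.40, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 21,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "l15_gc60", duplex_bp = 15, gc = 0.60, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 33,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "l25_gc84", duplex_bp = 25, gc = 0.84, chemistry = "DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 60,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "pna18_gc83", duplex_bp = 18, gc = 0.83, chemistry = "PNA_DNA",
               temperature_c = 25, speed_nm_s = 100, force_mean_pN = 95,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "dp16", duplex_bp = 15, gc = NA_real_, chemistry = "DNA",
               temperature_c = 37, speed_nm_s = 100, force_mean_pN = 16,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "dp30", duplex_bp = 18, gc = NA_real_, chemistry = "DNA",
               temperature_c = 37, speed_nm_s = 100, force_mean_pN = 30,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "dp46", duplex_bp = 18, gc = NA_real_, chemistry = "DNA",
               temperature_c = 37, speed_nm_s = 100, force_mean_pN = 46,
               force_sd_pN = NA_real_, n = NA_real_),
    data.frame(sensor = "dp58", duplex_bp = 25, gc = NA_real_, chemistry = "DNA",
               temperature_c = 37, speed_nm_s = 100, force_mean_pN = 58,
               force_sd_pN = NA_real_, n = NA_real_)
  )
  key <- paste(tab$sensor, tab$temperature_c, tab$speed_nm_s)
  stopifnot(!anyDuplicated(key), all(tab$force_mean_pN > 0))
  tab
}

# Measured force increments that take precedence over differences of nominal
# sensor thresholds. The dp16 -> dp30 step was measured directly as 13.2 pN.
measured_delta_F <- list("dp16:dp30" = 13.2)

#' Force step between two serial sensors
#'
#' Returns the force increase reported when a receptor's load crosses from
#' the low-threshold sensor to the high-threshold sensor. For the dp16/dp30
#' serial pair the directly measured step (13.2 pN) takes precedence over
#' the difference of nominal thresholds (30 - 16 = 14 pN); for other pairs
#' the difference of calibrated means is returned.
#'
#' @param from,to Sensor names present in [calibration_table()].
#' @param temperature_c,speed_nm_s Calibration condition keys (defaults:
#'   37 C, 100 nm/s, the cell-facing condition).
#' @return Force step in pN.
#' @export
ots_delta_F <- function(from = "dp16", to = "dp30",
                        temperature_c = 37, speed_nm_s = 100) {
  key <- paste(from, to, sep = ":")
  if (!is.null(measured_delta_F[[key]])) return(measured_delta_F[[key]])
  tab <- calibration_table()
  pick <- function(s) {
    row <- tab[tab$sensor == s & tab$temperature_c == temperature_c &
                 tab$speed_nm_s == speed_nm_s, ]
    if (nrow(row) != 1L) {
      stop(sprintf("no unique calibration row for sensor '%s' at %g C, %g nm/s",
                   s, temperature_c, speed_nm_s), call. = FALSE)
    }
    row$force_mean_pN
  }
  dF <- pick(to) - pick(from)
  if (dF <= 0) stop("'to' sensor must have the higher threshold", call. = FALSE)
  dF
}
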