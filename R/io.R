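#' Write a movie stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are written in T-major order (frame 1 channel 1, frame 1 channel
#' 2, ...). Photon counts are stored as 16-bit grayscale, the standard
#' camera format; integer counts up to 65535 round-trip exactly.
#' Acquisition metadata (pixel size, frame interval, channel names, axis
#' order) goes into a `<path>.yaml` sidecar.
#'
#' @param movie A `MovieStack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "MovieStack"))
  d <- dim(movie$pixels)
  if (any(movie$pixels < 0) || max(movie$pixels) > 65535) {
    stop("pixel values outside the 16-bit range [0, 65535]", call. = FALSE)
  }
  pages <- vector("list", d[1] * d[2])
  i <- 1L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pages[[i]] <- movie$pixels[t, ch, , ] / 65535
      i <- i + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(axes = "TCYX",
               n_frames = d[1], n_channels = d[2],
               height_px = d[3], width_px = d[4],
               pixel_size_nm = movie$pixel_size,
               frame_interval_s = movie$frame_interval,
               channel_names = as.list(movie$channel_names))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a movie stack written by [write_movie()]
#'
#' @param path TIFF path; `<path>.yaml` must exist and carry the keys
#'   `axes`, `n_frames`, `n_channels`, `pixel_size_nm`, `frame_interval_s`,
#'   `channel_names`.
#' @return A `MovieStack`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  sidecar <- paste0(path, ".yaml")
  required <- c("axes", "n_frames", "n_channels", "pixel_size_nm",
                "frame_interval_s", "channel_names")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing metadata sidecar '%s'; required keys: %s",
                 sidecar, paste(required, collapse = ", ")), call. = FALSE)
  }
  meta <- yaml::read_yaml(sidecar)
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop(sprintf("metadata sidecar is missing key(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!identical(meta$axes, "TCYX")) {
    stop(sprintf("unsupported axis order '%s' (expected TCYX)", meta$axes),
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  n_t <- meta$n_frames; n_c <- meta$n_channels
  if (length(pages) != n_t * n_c) {
    stop(sprintf("page count %d does not match %d frames x %d channels",
                 length(pages), n_t, n_c), call. = FALSE)
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  pixels <- array(0, dim = c(n_t, n_c, H, W))
  i <- 1L
  for (t in seq_len(n_t)) {
    for (ch in seq_len(n_c)) {
      pixels[t, ch, , ] <- round(pages[[i]] * 65535)
      i <- i + 1L
    }
  }
  movie_stack(pixels, pixel_size = meta$pixel_size_nm,
              frame_interval = meta$frame_interval_s,
              channel_names = unlist(meta$channel_names))
}

# CSV writers carry a '# key: value' comment header with units; readers
# skip comment lines.

write_csv_units <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  for (u in units) writeLines(paste0("# ", u), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read activation ground truth as CSV
#'
#' One row per event: position (px), channel onsets (s, `t_on_B_s` empty
#' when censored) and the censoring flag.
#'
#' @param truth Events from [simulate_activation_events()].
#' @param path CSV path.
#' @return The path (write) or a data.frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  write_csv_units(truth, path,
                  c("positions: px (0-based)", "times: s",
                    "censored: t_on_B beyond movie end"))
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read spot tracks as CSV
#'
#' @param tracks A `SpotTracks` table from [link_tracks()].
#' @param path CSV path.
#' @return The path (write) or a data.frame (read).
#' @export
write_tracks <- function(tracks, path) {
  write_csv_units(as.data.frame(tracks), path,
                  c("positions: px (0-based)", "t_on, t_off: s",
                    "open: track alive at movie end (right-censored)"))
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
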