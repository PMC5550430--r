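## Reading and writing movies (multi-page float TIFF + JSON sidecar), masks,
## traces and fit bundles.

#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages. Because the TIFF writer
#' stores values in [0, 1], each movie is min/max-normalised on write and the
#' offset/scale recorded in the sidecar, so the round trip is exact to 32-bit
#' float relative precision. The sidecar (`<path>.json`) carries frame times,
#' pixel pitch, sweep ids, the value transform and the movie class; the mask
#' is stored alongside as an 8-bit TIFF.
#'
#' @param movie a [fluo_movie()] or [dff_movie()].
#' @param path output TIFF path; sidecar and mask paths are derived from it.
#' @return (write) the path, invisibly; (read) the movie.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "iw_movie"))
  d <- dim(movie$frames)
  lo <- min(movie$frames, na.rm = TRUE)
  hi <- max(movie$frames, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1]), function(t) {
    f <- (movie$frames[t, , ] - lo) / scale
    f[is.na(f)] <- 0
    f
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  tiff::writeTIFF(movie$mask * 1.0, mask_path, bits.per.sample = 8L)
  meta <- list(class = class(movie)[1],
               frame_times_s = movie$frame_times,
               pixel_pitch_mm = movie$pixel_pitch,
               sweep_ids = movie$sweep_ids,
               value_offset = lo, value_scale = scale,
               mask_path = basename(mask_path),
               shape = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("sidecar metadata (", basename(sidecar), ") is required",
         call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("frame_times_s", "pixel_pitch_mm", "value_offset",
                  "value_scale"))
    if (is.null(meta[[field]]))
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  if (!is.null(meta$shape) && !all(d == meta$shape))
    stop("TIFF shape does not match the sidecar", call. = FALSE)
  frames <- array(NA_real_, d)
  for (t in seq_len(d[1]))
    frames[t, , ] <- pages[[t]] * meta$value_scale + meta$value_offset
  mask <- NULL
  mask_path <- file.path(dirname(path), meta$mask_path %||% "")
  if (nzchar(meta$mask_path %||% "") && file.exists(mask_path))
    mask <- tiff::readTIFF(mask_path) > 0.5
  ctor <- if (identical(meta$class, "fluo_movie")) fluo_movie else dff_movie
  ctor(frames, meta$frame_times_s, meta$pixel_pitch_mm, mask = mask,
       sweep_ids = meta$sweep_ids)
}

#' Write / read a single-channel trace as CSV (time_s, value)
#'
#' @param x numeric trace.
#' @param rate sample rate in Hz.
#' @param path CSV path.
#' @return (read) list with `time_s`, `value`, `rate`.
#' @export
write_trace_csv <- function(x, rate, path) {
  utils::write.csv(data.frame(time_s = (seq_along(x) - 1) / rate, value = x),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  rate <- 1 / stats::median(diff(df$time_s))
  list(time_s = df$time_s, value = df$value, rate = rate)
}

#' Save a standing-wave fit bundle
#'
#' Writes the map as float TIFF, the time course and RMS residuals as CSV,
#' and the scalar diagnostics (variance explained, window) as JSON.
#'
#' @param fit a `standing_wave_fit`.
#' @param dir output directory (created if needed).
#' @param stem file stem, default "standing_wave".
#' @return the directory, invisibly.
#' @export
write_standing_wave <- function(fit, dir, stem = "standing_wave") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- fit$map
  lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  mm <- (m - lo) / scale; mm[is.na(mm)] <- 0
  suppressWarnings(tiff::writeTIFF(mm, file.path(dir, paste0(stem, "_map.tif")),
                                   bits.per.sample = 32L))
  utils::write.csv(data.frame(time_s = fit$times,
                              time_course = fit$time_course,
                              rms_residual = fit$rms_residual_series),
                   file.path(dir, paste0(stem, "_timecourse.csv")),
                   row.names = FALSE)
  jsonlite::write_json(list(variance_explained = fit$variance_explained,
                            window_s = fit$window,
                            map_offset = lo, map_scale = scale),
                       file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
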