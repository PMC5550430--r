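#' Fluorescence and dF/F movie containers
#'
#' A movie is stored as a 3-D numeric array `frames` with dimensions
#' (time, rows, cols), together with frame times (s), the pixel pitch (mm), a
#' per-frame sweep id and a logical cortex mask. `fluo_movie()` holds raw
#' fluorescence; `dff_movie()` holds normalised dF/F values and, when produced
#' by [compute_dff()], the per-sweep baseline images.
#'
#' @param frames 3-D array (time, rows, cols).
#' @param frame_times numeric vector of frame times in seconds, strictly
#'   increasing within each sweep.
#' @param pixel_pitch pixel size in mm.
#' @param mask logical matrix (rows x cols); defaults to all TRUE.
#' @param sweep_ids integer per-frame sweep id; defaults to a single sweep.
#' @param f0 optional baseline image(s) for `dff_movie`.
#' @return an object of class `fluo_movie` or `dff_movie`.
#' @export
fluo_movie <- function(frames, frame_times, pixel_pitch, mask = NULL,
                       sweep_ids = NULL) {
  new_movie(frames, frame_times, pixel_pitch, mask, sweep_ids, "fluo_movie")
}

#' @rdname fluo_movie
#' @export
dff_movie <- function(frames, frame_times, pixel_pitch, mask = NULL,
                      sweep_ids = NULL, f0 = NULL) {
  m <- new_movie(frames, frame_times, pixel_pitch, mask, sweep_ids, "dff_movie")
  m$f0 <- f0
  m
}

new_movie <- function(frames, frame_times, pixel_pitch, mask, sweep_ids, cls) {
  stopifnot(length(dim(frames)) == 3L)
  nt <- dim(frames)[1]
  if (length(frame_times) != nt)
    stop("frame_times length must match the number of frames", call. = FALSE)
  mask <- mask %||% matrix(TRUE, dim(frames)[2], dim(frames)[3])
  if (!all(dim(mask) == dim(frames)[2:3]))
    stop("mask shape must equal the frame shape", call. = FALSE)
  sweep_ids <- sweep_ids %||% rep(1L, nt)
  for (s in unique(sweep_ids)) {
    tt <- frame_times[sweep_ids == s]
    if (any(diff(tt) <= 0))
      stop("frame times must be strictly increasing within a sweep",
           call. = FALSE)
  }
  structure(list(frames = frames, frame_times = frame_times,
                 pixel_pitch = pixel_pitch, mask = mask,
                 sweep_ids = as.integer(sweep_ids)),
            class = c(cls, "iw_movie"))
}

#' @export
print.iw_movie <- function(x, ...) {
  d <- dim(x$frames)
  fr <- if (d[1] > 1) 1 / stats::median(diff(x$frame_times)) else NA
  cat(sprintf("<%s> %d frames of %d x %d px, ~%.1f Hz, %.3f mm/px, %d sweep(s)\n",
              class(x)[1], d[1], d[2], d[3], fr, x$pixel_pitch,
              length(unique(x$sweep_ids))))
  invisible(x)
}

## time x pixel matrix view (all pixels, column-major pixel order)
movie_matrix <- function(movie, frames_idx = NULL) {
  f <- movie$frames
  d <- dim(f)
  m <- matrix(f, d[1], d[2] * d[3])
  if (!is.null(frames_idx)) m <- m[frames_idx, , drop = FALSE]
  m
}

frame_rate <- function(movie) 1 / stats::median(diff(movie$frame_times))

## indices of frames within a [t0, t1] window
window_frames <- function(movie, window) {
  idx <- which(movie$frame_times >= window[1] & movie$frame_times <= window[2])
  if (!length(idx)) stop("empty frame window", call. = FALSE)
  idx
}

#' Compute dF/F with a percentile baseline
#'
#' Normalises a raw fluorescence movie as (F - F0) / F0, where F0 is a
#' per-pixel, per-sweep percentile of the pixel's trace (default the 20th).
#' Percentiles use the usual linear interpolation between order statistics
#' (type 7). Baselines are never shared across sweeps. Pixels whose baseline is
#' not positive are set to NA and flagged.
#'
#' @param movie a [fluo_movie()].
#' @param percentile baseline percentile as a fraction, default 0.20.
#' @return a [dff_movie()] with `f0` a list of per-sweep baseline images and an
#'   attribute `flagged` (logical matrix) marking pixels with F0 <= 0.
#' @examples
#' f <- array(rep(1:10, each = 1), c(10, 1, 1))
#' m <- fluo_movie(f, seq(0, 0.9, 0.1), 0.05)
#' compute_dff(m)$f0[[1]]  # 2.8, the interpolated 20th percentile of 1..10
#' @export
compute_dff <- function(movie, percentile = 0.20) {
  stopifnot(inherits(movie, "fluo_movie"))
  sweeps <- unique(movie$sweep_ids)
  for (s in sweeps)
    if (sum(movie$sweep_ids == s) < 10L)
      stop("each sweep needs at least 10 frames for a stable baseline",
           call. = FALSE)
  d <- dim(movie$frames)
  out <- array(NA_real_, d)
  f0_list <- list()
  flagged <- matrix(FALSE, d[2], d[3])
  X <- movie_matrix(movie)
  for (s in sweeps) {
    rows <- movie$sweep_ids == s
    f0 <- apply(X[rows, , drop = FALSE], 2, stats::quantile,
                probs = percentile, names = FALSE, type = 7)
    bad <- f0 <= 0
    flagged <- flagged | matrix(bad, d[2], d[3])
    f0[bad] <- NA_real_
    dff <- sweep(sweep(X[rows, , drop = FALSE], 2, f0, "-"), 2, f0, "/")
    out[rows, , ] <- array(dff, c(sum(rows), d[2], d[3]))
    f0_list[[as.character(s)]] <- matrix(f0, d[2], d[3])
  }
  res <- dff_movie(out, movie$frame_times, movie$pixel_pitch, movie$mask,
                   movie$sweep_ids, f0 = f0_list)
  attr(res, "flagged") <- flagged
  res
}

#' Maximum-projection image over a time window
#'
#' @param dff a [dff_movie()].
#' @param window numeric (t0, t1) in seconds; defaults to the whole movie.
#' @return matrix of per-pixel maxima of dF/F over the window.
#' @export
max_projection <- function(dff, window = NULL) {
  stopifnot(inherits(dff, "iw_movie"))
  window <- window %||% range(dff$frame_times)
  idx <- window_frames(dff, window)
  X <- movie_matrix(dff, idx)
  matrix(apply(X, 2, max), dim(dff$frames)[2], dim(dff$frames)[3])
}
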