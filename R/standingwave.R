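## Rank-1 standing-wave model: Movie = time course x map + residuals.

#' Fit the standing-wave (rank-1) model to an event movie
#'
#' Factorises the movie matrix (frames x masked pixels) into a single time
#' course times a single spatial map by singular value decomposition, which is
#' the least-squares rank-1 approximation. The map has unit Euclidean norm and
#' the scale is carried by the time course; the sign convention makes the time
#' course nonnegative at its absolute peak. Variance explained is computed on
#' the raw (uncentred) values over masked pixels:
#' 1 - ||residual||^2 / ||movie||^2.
#'
#' @param movie a [dff_movie()].
#' @param window numeric (t0, t1) fit window (>= 3 frames); defaults to the
#'   whole movie.
#' @return object of class `standing_wave_fit`: `map` (matrix, unit norm, NA
#'   off-mask), `time_course`, `times`, `variance_explained`,
#'   `residual` (frames x masked-pixel matrix), `rms_residual_series`,
#'   `mask`, `window`.
#' @export
fit_standing_wave <- function(movie, window = NULL) {
  stopifnot(inherits(movie, "iw_movie"))
  window <- window %||% range(movie$frame_times)
  idx <- window_frames(movie, window)
  if (length(idx) < 3) stop("fit window must span at least 3 frames",
                            call. = FALSE)
  keep <- as.vector(movie$mask)
  X <- movie_matrix(movie, idx)[, keep, drop = FALSE]
  X[is.na(X)] <- 0
  total <- sum(X^2)
  if (total == 0) stop("fit undefined: window is identically zero",
                       call. = FALSE)
  sv <- svd(X, nu = 1, nv = 1)
  tc <- sv$u[, 1] * sv$d[1]
  mp <- sv$v[, 1]
  if (tc[which.max(abs(tc))] < 0) { tc <- -tc; mp <- -mp }
  R <- X - tc %o% mp
  ve <- 1 - sum(R^2) / total
  map <- matrix(NA_real_, dim(movie$frames)[2], dim(movie$frames)[3])
  map[movie$mask] <- mp
  structure(list(map = map, time_course = tc, times = movie$frame_times[idx],
                 variance_explained = ve, residual = R,
                 rms_residual_series = sqrt(rowMeans(R^2)),
                 mask = movie$mask, window = window),
            class = "standing_wave_fit")
}

#' @export
print.standing_wave_fit <- function(x, ...) {
  cat(sprintf(
    "<standing_wave_fit> %d frames, %d masked px | variance explained %.1f%% | max RMS residual %.3f dF/F\n",
    length(x$time_course), sum(x$mask), 100 * x$variance_explained,
    max(x$rms_residual_series)))
  invisible(x)
}

#' Fit a fixed spatial map with a free time course
#'
#' Constrained variant used for seizures: the spatial map is held at the
#' (interictal) template and only the per-frame coefficient is fitted, by the
#' closed-form projection <map, frame> / <map, map>.
#'
#' @param movie a [dff_movie()].
#' @param map template map (matrix over the full grid, NA allowed off-mask).
#' @param window numeric (t0, t1); defaults to the whole movie.
#' @return object of class `standing_wave_fit` (same fields; `map` is the
#'   renormalised template).
#' @export
fit_fixed_map <- function(movie, map, window = NULL) {
  stopifnot(inherits(movie, "iw_movie"))
  window <- window %||% range(movie$frame_times)
  idx <- window_frames(movie, window)
  keep <- as.vector(movie$mask)
  m <- as.vector(map)[keep]
  m[is.na(m)] <- 0
  nm2 <- sum(m^2)
  if (nm2 == 0) stop("template map is identically zero", call. = FALSE)
  m <- m / sqrt(nm2)
  X <- movie_matrix(movie, idx)[, keep, drop = FALSE]
  X[is.na(X)] <- 0
  tc <- drop(X %*% m)
  R <- X - tc %o% m
  total <- sum(X^2)
  ve <- if (total > 0) 1 - sum(R^2) / total else NA_real_
  full_map <- matrix(NA_real_, dim(movie$frames)[2], dim(movie$frames)[3])
  full_map[movie$mask] <- m
  structure(list(map = full_map, time_course = tc,
                 times = movie$frame_times[idx],
                 variance_explained = ve, residual = R,
                 rms_residual_series = sqrt(rowMeans(R^2)),
                 mask = movie$mask, window = window),
            class = "standing_wave_fit")
}

#' Average the spatial map across event fits
#'
#' Sign-aligns the maps (an SVD map is defined up to sign), averages and
#' renormalises, and summarises fit quality with an empirical 2nd-98th
#' percentile band of variance explained across events.
#'
#' @param fits list of `standing_wave_fit` objects with matching geometry.
#' @return list with `map` (unit-norm mean map), `ve_band` (2nd and 98th
#'   percentiles), `ve` (per-event values).
#' @export
average_event_map <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  dims <- vapply(fits, function(f) dim(f$map), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("fits have mismatching geometry", call. = FALSE)
  ref <- as.vector(fits[[1]]$map)
  acc <- 0
  for (f in fits) {
    v <- as.vector(f$map)
    s <- sum(v * ref, na.rm = TRUE)
    acc <- acc + if (s < 0) -v else v
  }
  acc <- acc / length(fits)
  nrm <- sqrt(sum(acc^2, na.rm = TRUE))
  mean_map <- matrix(acc / nrm, dims[1, 1], dims[2, 1])
  ve <- vapply(fits, function(f) f$variance_explained, numeric(1))
  list(map = mean_map,
       ve_band = stats::quantile(ve, c(0.02, 0.98), names = FALSE, type = 7),
       ve = ve)
}

#' Per-frame RMS residual of a standing-wave fit
#'
#' @param fit a `standing_wave_fit` (from [fit_standing_wave()] or
#'   [fit_fixed_map()]).
#' @return numeric vector, RMS over masked pixels per frame, in dF/F units.
#' @export
residual_timecourse <- function(fit) {
  stopifnot(inherits(fit, "standing_wave_fit"))
  fit$rms_residual_series
}
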