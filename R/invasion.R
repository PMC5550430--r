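## Focus localisation, seizure recruitment, delay-to-invasion maps and the
## speed regression with its retinotopic residual analysis.

#' Localise the epileptic focus from event onsets
#'
#' For each event, pixels exceeding 60% of the class peak dF/F within the
#' first 500 ms after onset are selected and the centre of mass of that area
#' is taken as the event's initiation site. Across events the mean centre and
#' the RMS dispersion radius are reported.
#'
#' @param movies list of [dff_movie()]s, one per event, each starting at the
#'   event onset (or a single movie used with `windows`).
#' @param windows optional list of (t0, t1) windows, one per movie; default
#'   first 500 ms of each movie.
#' @param class_peak optional peak dF/F of the event class; default the
#'   maximum over all events.
#' @param threshold fraction of the class peak, default 0.6.
#' @param early_s initial window length in seconds, default 0.5.
#' @return list with `focus_rc` (mean centre, row/col, fractional),
#'   `dispersion_mm` (RMS radius), `centers` (per-event), `n_used`,
#'   `n_skipped`.
#' @export
localize_focus <- function(movies, windows = NULL, class_peak = NULL,
                           threshold = 0.6, early_s = 0.5) {
  if (inherits(movies, "iw_movie")) movies <- list(movies)
  if (is.null(class_peak))
    class_peak <- max(vapply(movies, function(m)
      max(movie_matrix(m)[, as.vector(m$mask)], na.rm = TRUE), numeric(1)))
  centers <- list(); skipped <- 0L
  for (i in seq_along(movies)) {
    m <- movies[[i]]
    w <- if (!is.null(windows)) windows[[i]] else
      c(m$frame_times[1], m$frame_times[1] + early_s)
    mx <- max_projection(m, w)
    mx[!m$mask] <- -Inf
    sel <- which(mx > threshold * class_peak, arr.ind = TRUE)
    if (!nrow(sel)) {
      warning(sprintf("event %d has no suprathreshold pixels; skipped", i),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    centers[[length(centers) + 1]] <- colMeans(sel)
  }
  if (!length(centers))
    stop("no event yielded suprathreshold pixels", call. = FALSE)
  C <- do.call(rbind, centers)
  mu <- colMeans(C)
  pitch <- movies[[1]]$pixel_pitch
  disp <- sqrt(mean(rowSums(sweep(C, 2, mu)^2))) * pitch
  list(focus_rc = mu, dispersion_mm = disp, centers = C,
       n_used = nrow(C), n_skipped = skipped)
}

#' Pixels recruited to a seizure
#'
#' A pixel is recruited when its maximal dF/F during the event exceeds 30% of
#' the peak fluorescence recorded at the focus.
#'
#' @param dff a [dff_movie()] of the seizure.
#' @param window numeric (t0, t1) event window; default the whole movie.
#' @param focus_peak peak dF/F at the focus (> 0).
#' @param threshold fraction of the focus peak, default 0.3.
#' @return logical matrix (FALSE off-mask).
#' @export
recruited_mask <- function(dff, window = NULL, focus_peak, threshold = 0.3) {
  if (focus_peak <= 0) stop("focus peak must be > 0", call. = FALSE)
  mx <- max_projection(dff, window)
  rec <- mx > threshold * focus_peak
  rec & dff$mask
}

#' Delay to seizure invasion per pixel
#'
#' For every recruited pixel, the delay is the time at which its fluorescence
#' first reaches 60% of its own maximum during the event, linearly
#' interpolated between the bracketing frames, measured from the
#' electrographic onset. The criterion is scale-free per pixel, so per-pixel
#' amplitude differences do not bias the map.
#'
#' @param dff a [dff_movie()] of the seizure.
#' @param onset_s electrographic onset time (s, on the movie clock).
#' @param recruited logical matrix from [recruited_mask()]; default all masked
#'   pixels.
#' @param window numeric (t0, t1); default onset to end of movie.
#' @param threshold fraction of the pixel's own maximum, default 0.6.
#' @return matrix of delays in seconds (NA where not recruited).
#' @export
compute_delay_map <- function(dff, onset_s, recruited = NULL, window = NULL,
                              threshold = 0.6) {
  stopifnot(inherits(dff, "iw_movie"))
  window <- window %||% c(onset_s, max(dff$frame_times))
  idx <- window_frames(dff, window)
  tt <- dff$frame_times[idx]
  X <- movie_matrix(dff, idx)
  recruited <- recruited %||% dff$mask
  pix <- which(as.vector(recruited))
  delays <- rep(NA_real_, prod(dim(dff$frames)[2:3]))
  for (p in pix) {
    tr <- X[, p]
    mx <- max(tr, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) next
    delays[p] <- first_crossing(tr, tt, threshold * mx) - onset_s
  }
  matrix(delays, dim(dff$frames)[2], dim(dff$frames)[3])
}

#' Delay-vs-distance regression across seizures
#'
#' Per-pixel delays are averaged across seizures, binned by cortical distance
#' from the focus (default 0.1 mm bins), and the bin-mean delays are fitted by
#' unweighted ordinary least squares against bin-mean distance. The
#' propagation speed is 1 / slope. The pixelwise Pearson correlation between
#' delay and distance, the per-pixel residuals from the binned line, and the
#' correlation of those residuals with retinotopic (azimuthal) distance from
#' the focus are also returned.
#'
#' @param delay_maps list of delay matrices (one per seizure) or a single
#'   matrix.
#' @param geom a `cortex_geometry` (provides distances and retinotopy), or
#'   NULL if `distance_mm` and `retinotopic_deg` are given.
#' @param focus_rc focus (row, col); default the geometry focus.
#' @param distance_mm optional distance image overriding the geometry.
#' @param retinotopic_deg optional azimuthal-distance image.
#' @param bin_mm distance bin width, default 0.1 mm.
#' @param min_pixels minimum recruited pixels, default 10.
#' @return object of class `speed_fit`: slope (s/mm), intercept (s), speed
#'   (mm/s), `r_delay_distance`, `r_resid_retinotopy`, `residual_map`,
#'   `mean_delay`, `bins` (data.frame), `n_pixels`.
#' @export
speed_regression <- function(delay_maps, geom = NULL, focus_rc = NULL,
                             distance_mm = NULL, retinotopic_deg = NULL,
                             bin_mm = 0.1, min_pixels = 10) {
  if (is.matrix(delay_maps)) delay_maps <- list(delay_maps)
  D <- Reduce(`+`, lapply(delay_maps, function(m) ifelse(is.na(m), 0, m)))
  Nn <- Reduce(`+`, lapply(delay_maps, function(m) !is.na(m)))
  mean_delay <- ifelse(Nn > 0, D / Nn, NA_real_)
  if (!is.null(geom)) {
    focus_rc <- focus_rc %||% geom$focus_rc
    distance_mm <- distance_mm %||%
      dist_from(geom$grid_shape, geom$pixel_pitch, focus_rc)
    retinotopic_deg <- retinotopic_deg %||% abs(geom$azimuth -
                                                  geom$focus_azimuth)
  }
  if (is.null(distance_mm))
    stop("provide either a geometry or a distance image", call. = FALSE)
  ok <- is.finite(mean_delay) & is.finite(distance_mm)
  if (sum(ok) < min_pixels)
    stop("too few recruited pixels for the regression", call. = FALSE)
  d <- distance_mm[ok]; y <- mean_delay[ok]
  bins <- floor(d / bin_mm)
  bx <- tapply(d, bins, mean); by <- tapply(y, bins, mean)
  fit <- stats::lm(by ~ bx)
  slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
  speed <- if (slope > 0) 1 / slope else NA_real_
  r_dd <- stats::cor(y, d)
  residual_map <- mean_delay - (icpt + slope * distance_mm)
  residual_map[!ok] <- NA_real_
  r_rr <- NA_real_
  if (!is.null(retinotopic_deg))
    r_rr <- stats::cor(residual_map[ok], retinotopic_deg[ok])
  structure(list(slope_s_mm = slope, intercept_s = icpt, speed_mm_s = speed,
                 r_delay_distance = r_dd, r_resid_retinotopy = r_rr,
                 residual_map = residual_map, mean_delay = mean_delay,
                 bins = data.frame(distance_mm = as.numeric(bx),
                                   delay_s = as.numeric(by)),
                 n_pixels = sum(ok)),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf(
    "<speed_fit> speed %.3f mm/s (slope %.3f s/mm) | r(delay, distance) = %.3f | r(residual, retinotopy) = %.3f | %d px\n",
    x$speed_mm_s, x$slope_s_mm, x$r_delay_distance, x$r_resid_retinotopy,
    x$n_pixels))
  invisible(x)
}
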