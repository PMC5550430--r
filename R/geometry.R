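#' Build a synthetic two-area retinotopic cortex
#'
#' Constructs a parametric model of a widefield imaging field of view that
#' contains primary visual cortex (V1) and the lateromedial area (LM) side by
#' side, with mirrored retinotopic azimuth gradients: azimuth falls linearly
#' across V1 towards the V1/LM border (the vertical meridian) and rises again
#' across LM. Elevation varies linearly along the orthogonal (row) axis in both
#' areas. The epileptic focus is placed inside V1 at a configurable preferred
#' azimuth (default 93 degrees) and at the centre of the elevation span.
#'
#' The geometry is deliberately parametric rather than atlas-derived: area
#' outlines are axis-aligned bands of the grid (optionally leaving a background
#' margin), which keeps the generator free of registration machinery while
#' preserving the two features the downstream analyses rely on, namely mirrored
#' azimuth gradients and a homotopic partner location in LM for any V1 site.
#'
#' @param grid_shape integer (rows, cols) of the pixel grid; at least 32 x 32.
#' @param pixel_pitch pixel size in mm.
#' @param v1_width width of V1 in mm, measured from the left edge of the grid.
#' @param lm_width width of LM in mm; defaults to the rest of the grid. If
#'   `v1_width + lm_width` is less than the grid width the remainder is labelled
#'   background (label 0).
#' @param focus_azimuth preferred azimuth of the focus in degrees.
#' @param azimuth_span stimulus azimuth span in degrees, default c(0, 140).
#' @param elevation_span stimulus elevation span in degrees, default c(-30, 30).
#' @param seed optional integer; the construction is deterministic, the seed is
#'   accepted so that configuration records are self-contained.
#' @return an object of class `cortex_geometry`: list with `grid_shape`,
#'   `pixel_pitch`, `area` (integer matrix, 0 = background, 1 = V1, 2 = LM),
#'   `azimuth` and `elevation` (degree matrices), `focus_rc` (row, col),
#'   `focus_azimuth`, `azimuth_span`, `elevation_span`.
#' @examples
#' geom <- make_geometry()
#' table(geom$area)
#' @export
make_geometry <- function(grid_shape = c(64, 64), pixel_pitch = 0.05,
                          v1_width = 2.2, lm_width = NULL,
                          focus_azimuth = 93,
                          azimuth_span = c(0, 140),
                          elevation_span = c(-30, 30),
                          seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32L))
    stop("grid must be at least 32 x 32", call. = FALSE)
  stopifnot_scalar(pixel_pitch, "pixel_pitch", positive = TRUE)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  fov_x <- (nc - 1) * pixel_pitch
  lm_width <- lm_width %||% (fov_x - v1_width)
  if (v1_width <= 0 || lm_width <= 0)
    stop("invalid geometry: both areas must have positive width", call. = FALSE)
  if (v1_width + lm_width > fov_x + pixel_pitch / 2)
    stop("invalid geometry: areas overlap or exceed the grid", call. = FALSE)

  co <- pixel_coords(grid_shape, pixel_pitch)
  area <- matrix(0L, nr, nc)
  area[co$x < v1_width] <- 1L
  area[co$x >= v1_width & co$x <= v1_width + lm_width + pixel_pitch / 2] <- 2L

  lo <- azimuth_span[1]; hi <- azimuth_span[2]
  span <- hi - lo
  az <- matrix(NA_real_, nr, nc)
  v1 <- area == 1L; lm <- area == 2L
  ## mirrored gradients: azimuth falls to `lo` at the V1/LM border, rises in LM
  az[v1] <- lo + span * (v1_width - co$x[v1]) / v1_width
  az[lm] <- lo + span * (co$x[lm] - v1_width) / lm_width
  az <- pmin(pmax(az, lo), hi)

  el <- matrix(elevation_span[1], nr, nc) +
    (elevation_span[2] - elevation_span[1]) * co$y / max(co$y)

  if (focus_azimuth < lo || focus_azimuth > hi)
    stop("focus azimuth outside the stimulus span", call. = FALSE)
  focus_col <- round((v1_width - (focus_azimuth - lo) / span * v1_width) /
                       pixel_pitch) + 1L
  focus_col <- max(1L, min(nc, focus_col))
  focus_row <- as.integer(round(nr / 2))
  if (area[focus_row, focus_col] != 1L)
    stop("invalid geometry: focus does not fall inside V1", call. = FALSE)

  structure(list(
    grid_shape = grid_shape, pixel_pitch = pixel_pitch,
    area = area, azimuth = az, elevation = el,
    focus_rc = c(focus_row, focus_col),
    focus_azimuth = focus_azimuth,
    azimuth_span = azimuth_span, elevation_span = elevation_span,
    v1_width = v1_width, lm_width = lm_width, seed = seed
  ), class = "cortex_geometry")
}

#' @export
print.cortex_geometry <- function(x, ...) {
  cat(sprintf("<cortex_geometry> %d x %d px, %.3f mm/px (FOV %.2f x %.2f mm)\n",
              x$grid_shape[1], x$grid_shape[2], x$pixel_pitch,
              (x$grid_shape[1] - 1) * x$pixel_pitch,
              (x$grid_shape[2] - 1) * x$pixel_pitch))
  cat(sprintf("  V1 %.2f mm | LM %.2f mm | background %d px\n",
              x$v1_width, x$lm_width, sum(x$area == 0L)))
  cat(sprintf("  focus at (row %d, col %d), azimuth %.1f deg\n",
              x$focus_rc[1], x$focus_rc[2], x$focus_azimuth))
  invisible(x)
}

## cortex mask (V1 + LM) as a logical matrix
geometry_mask <- function(geom) geom$area > 0L

## homotopic partner of the focus: the LM pixel with the closest azimuth,
## ties broken by elevation proximity to the focus
homotopic_seed <- function(geom) {
  lm <- which(geom$area == 2L)
  if (!length(lm)) stop("geometry has no LM pixels", call. = FALSE)
  dr <- abs(geom$azimuth[lm] - geom$focus_azimuth)
  cand <- lm[dr == min(dr)]
  fel <- geom$elevation[geom$focus_rc[1], geom$focus_rc[2]]
  best <- cand[which.min(abs(geom$elevation[cand] - fel))]
  nr <- geom$grid_shape[1]
  c(row = (best - 1L) %% nr + 1L, col = (best - 1L) %/% nr + 1L)
}

#' Plant a per-pixel delay-to-invasion field
#'
#' Generative model of slow seizure spread combining the two routes the
#' analyses are designed to separate. A contiguous front travels radially from
#' the focus at `speed`. A homotopic route seeds a secondary focus at the LM
#' pixel retinotopically closest to the focus after `jump_delay`, from which
#' activity spreads contiguously at the same speed; each pixel takes whichever
#' route is faster. On top of the winning route, invasion is slowed in
#' proportion to the pixel's retinotopic (azimuthal) distance from the focus by
#' `retinotopic_slowdown` seconds per degree, expressing that homotopic
#' connectivity speeds the front through territories whose visual-field
#' preference matches the focus. With `homotopic = FALSE` both homotopic
#' mechanisms are disabled and the field reduces to distance / speed.
#'
#' @param geom a `cortex_geometry`.
#' @param speed contiguous front speed in mm/s (> 0).
#' @param jump_delay latency of the homotopic LM seed in seconds.
#' @param homotopy_width width (degrees) of the homotopic kernel used by the
#'   event footprint; carried in the returned attributes for bookkeeping.
#' @param retinotopic_slowdown extra delay per degree of azimuthal distance
#'   from the focus (s/deg).
#' @param homotopic logical; disable to obtain the purely contiguous field.
#' @param origin_rc optional (row, col) origin overriding the geometry focus.
#' @return matrix of delays in seconds (NA outside the cortex mask), with
#'   attributes `lm_seed_rc` and `params`.
#' @examples
#' geom <- make_geometry()
#' d <- plant_delay_field(geom, speed = 0.5, homotopic = FALSE)
#' d[geom$focus_rc[1], geom$focus_rc[2]]  # 0 at the focus
#' @export
plant_delay_field <- function(geom, speed = 0.48, jump_delay = 4.0,
                              homotopy_width = 25,
                              retinotopic_slowdown = 0.008,
                              homotopic = TRUE, origin_rc = NULL) {
  stopifnot(inherits(geom, "cortex_geometry"))
  if (!is.numeric(speed) || speed <= 0)
    stop("speed must be > 0", call. = FALSE)
  origin <- origin_rc %||% geom$focus_rc
  d <- dist_from(geom$grid_shape, geom$pixel_pitch, origin)
  delay <- d / speed
  seed_rc <- NULL
  if (homotopic) {
    seed_rc <- homotopic_seed(geom)
    dl <- dist_from(geom$grid_shape, geom$pixel_pitch, seed_rc)
    delay <- pmin(delay, jump_delay + dl / speed)
    retd <- abs(geom$azimuth - geom$focus_azimuth)
    delay <- delay + retinotopic_slowdown * retd
  }
  delay[!geometry_mask(geom)] <- NA_real_
  attr(delay, "lm_seed_rc") <- seed_rc
  attr(delay, "params") <- list(speed = speed, jump_delay = jump_delay,
                                homotopy_width = homotopy_width,
                                retinotopic_slowdown = retinotopic_slowdown,
                                homotopic = homotopic)
  delay
}
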