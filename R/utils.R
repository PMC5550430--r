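## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-pi, pi]
#'
#' Half-open convention: exactly -pi maps to +pi, so a lag of exactly half a
#' period is reported as +T/2.
#' @param x angles in radians.
#' @return wrapped angles in (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

## pixel-centre coordinate grids in mm, (row, col) 0-based at the top-left
pixel_coords <- function(grid_shape, pixel_pitch) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  list(
    x = matrix(rep((seq_len(nc) - 1) * pixel_pitch, each = nr), nr, nc),
    y = matrix(rep((seq_len(nr) - 1) * pixel_pitch, nc), nr, nc)
  )
}

## Euclidean distance image (mm) from a (row, col) pixel
dist_from <- function(grid_shape, pixel_pitch, rc) {
  co <- pixel_coords(grid_shape, pixel_pitch)
  x0 <- (rc[2] - 1) * pixel_pitch
  y0 <- (rc[1] - 1) * pixel_pitch
  sqrt((co$x - x0)^2 + (co$y - y0)^2)
}

## first linearly interpolated upward crossing of `level` in `trace`
## sampled at `times`; NA if never crossed
first_crossing <- function(trace, times, level) {
  above <- trace >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  v0 <- trace[i - 1]; v1 <- trace[i]
  if (v1 == v0) return(t1)
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
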