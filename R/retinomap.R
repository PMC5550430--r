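## Retinotopic mapping from periodic-stimulus sessions, and the V1 -> LM ROI
## path used for event profiles.

#' Per-pixel response amplitude at the second harmonic of the reversal
#'
#' Contrast-reversing gratings drive visual cortex at twice the reversal
#' frequency. For each pixel, the Fourier component of its trace at exactly
#' 2 x reversal_rate over the stimulus epoch is extracted; the returned image
#' holds the amplitude (2 |X(f)| / N), so a trace A cos(2 pi f t) yields A.
#'
#' @param dff a [dff_movie()] covering the stimulus epoch.
#' @param reversal_rate grating reversal rate in Hz.
#' @return matrix of response amplitudes (dF/F).
#' @export
second_harmonic_power <- function(dff, reversal_rate) {
  stopifnot(inherits(dff, "iw_movie"))
  fr <- frame_rate(dff)
  f2 <- 2 * reversal_rate
  if (fr < 2 * f2)
    stop("frame rate too low for the second harmonic (aliasing)",
         call. = FALSE)
  tt <- dff$frame_times
  if ((max(tt) - min(tt)) < 2 / f2)
    stop("stimulus epoch must span at least 2 cycles of the second harmonic",
         call. = FALSE)
  X <- movie_matrix(dff)
  X[is.na(X)] <- 0
  ph <- exp(-2i * pi * f2 * tt)
  amp <- 2 * Mod(drop(ph %*% X)) / length(tt)
  matrix(amp, dim(dff$frames)[2], dim(dff$frames)[3])
}

#' Fit Gaussian position tuning with a shared width
#'
#' For each pixel, response amplitudes at the stimulus positions are fitted
#' with a Gaussian tuning curve g * exp(-(theta - c)^2 / (2 sigma_t^2)). The
#' width sigma_t is shared across all pixels of the session and chosen by grid
#' search (default 5-60 deg in 1 deg steps) to minimise the summed squared
#' error across pixels; the per-pixel centre is found on a 1-deg grid over the
#' stimulus span and refined by parabolic interpolation. Pixels with an
#' all-zero or flat response are flagged missing.
#'
#' @param amplitudes pixels x positions matrix of response amplitudes (>= 0).
#' @param positions stimulus azimuths in degrees (>= 3).
#' @param sigma_grid candidate shared widths in degrees.
#' @param span centre search span, defaults to the range of `positions`
#'   extended by 20 degrees each side.
#' @return object of class `tuning_fit`: `preferred` (deg, NA where missing),
#'   `gain`, `sigma_t`, `sse`, `positions`.
#' @export
fit_position_tuning <- function(amplitudes, positions, sigma_grid = 5:60,
                                span = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (length(positions) < 3)
    stop("need at least 3 stimulus positions", call. = FALSE)
  if (ncol(amplitudes) != length(positions))
    stop("amplitude columns must match positions", call. = FALSE)
  span <- span %||% (range(positions) + c(-20, 20))
  centers <- seq(span[1], span[2], by = 1)
  P <- nrow(amplitudes)
  resp_sd <- apply(amplitudes, 1, stats::sd)
  ok <- is.finite(resp_sd) & resp_sd > 0
  A <- amplitudes[ok, , drop = FALSE]
  a2 <- rowSums(A^2)

  best <- NULL
  for (sg in sigma_grid) {
    ## model matrix: centres x positions
    M <- exp(-outer(centers, positions, "-")^2 / (2 * sg^2))
    m2 <- rowSums(M^2)
    G <- A %*% t(M)                      # pixels x centres inner products
    G[G < 0] <- 0
    SSE <- -sweep(G^2, 2, m2, "/")       # -g^2 |m|^2 (plus |A|^2, constant)
    ci <- max.col(-SSE, ties.method = "first")
    sse_pix <- a2 + SSE[cbind(seq_len(nrow(A)), ci)]
    tot <- sum(sse_pix)
    if (is.null(best) || tot < best$tot)
      best <- list(tot = tot, sg = sg, ci = ci, M = M, m2 = m2, G = G)
  }

  ## parabolic refinement of the centre around the grid optimum
  ci <- best$ci
  gain_grid <- best$G / matrix(best$m2, nrow(A), length(centers), byrow = TRUE)
  score <- best$G^2 / matrix(best$m2, nrow(A), length(centers), byrow = TRUE)
  pref <- centers[ci]
  interior <- ci > 1 & ci < length(centers)
  if (any(interior)) {
    i <- which(interior)
    y0 <- score[cbind(i, ci[i] - 1L)]
    y1 <- score[cbind(i, ci[i])]
    y2 <- score[cbind(i, ci[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
    pref[i] <- pref[i] + pmax(-0.5, pmin(0.5, shift))
  }
  preferred <- rep(NA_real_, P); gain <- rep(NA_real_, P)
  preferred[ok] <- pref
  gain[ok] <- gain_grid[cbind(seq_len(nrow(A)), ci)]
  structure(list(preferred = preferred, gain = gain, sigma_t = best$sg,
                 sse = best$tot, positions = positions),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "<tuning_fit> %d pixels (%d responsive) | shared sigma_t %.0f deg | SSE %.4g\n",
    length(x$preferred), sum(is.finite(x$preferred)), x$sigma_t, x$sse))
  invisible(x)
}

#' Map preferred azimuth from a retinotopy session
#'
#' Convenience wrapper: second-harmonic amplitudes for each stimulus position,
#' then the shared-width Gaussian tuning fit, returned as a preferred-azimuth
#' image.
#'
#' @param session list as returned by [render_retinotopy_session()] (fields
#'   `movies` and `stimuli`), or any list of [dff_movie()]s plus a vector of
#'   stimulus azimuths.
#' @param stim_azimuths stimulus azimuths; taken from `session$stimuli` if
#'   absent.
#' @return list with `azimuth` (matrix, deg), `fit` (the `tuning_fit`) and
#'   `amplitude` (pixels x positions matrix).
#' @export
map_retinotopy <- function(session, stim_azimuths = NULL) {
  movies <- session$movies %||% session
  stim_azimuths <- stim_azimuths %||% session$stimuli$azimuth_deg
  rev_rate <- session$stimuli$reversal_rate_hz[1] %||% 2
  amps <- vapply(movies, function(m)
    as.vector(second_harmonic_power(m, rev_rate)),
    numeric(prod(dim(movies[[1]]$frames)[2:3])))
  fit <- fit_position_tuning(amps, stim_azimuths)
  d <- dim(movies[[1]]$frames)[2:3]
  list(azimuth = matrix(fit$preferred, d[1], d[2]), fit = fit,
       amplitude = amps)
}

## 3x3 median smoothing (edge-replicated), used before gradient estimation
median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  out <- m
  for (i in 1:nr) for (j in 1:nc)
    out[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)], na.rm = TRUE)
  out
}

#' Build the V1 -> LM ROI path along the azimuth gradient
#'
#' Starting at the focus, marches in the direction of maximal change of
#' preferred azimuth (estimated on a 3x3 median-smoothed map), constrained to
#' stay within an elevation iso-band around the focus elevation, until it has
#' crossed into LM and reached the far LM edge. Of the two gradient
#' directions, the one whose ray reaches LM is taken. Returns ordered ROI
#' centres with cortical distance from the focus (path arc length) and the
#' local preferred azimuth.
#'
#' @param azimuth preferred-azimuth image (deg), e.g. from [map_retinotopy()].
#' @param area area-label image (0 background, 1 V1, 2 LM).
#' @param elevation elevation image (deg); if NULL the band constraint is
#'   skipped (appropriate when elevation is constant along rows).
#' @param focus_rc focus (row, col).
#' @param pixel_pitch mm per pixel.
#' @param roi_radius ROI radius in mm, default 0.1.
#' @param step spacing of ROI centres in mm, default 0.15 (consecutive
#'   centres stay within 2 x roi_radius).
#' @param elev_tol elevation iso-band half-width in degrees, default 5.
#' @return object of class `roi_path`: data.frame with row, col, distance_mm,
#'   azimuth_deg, area plus attributes `roi_radius_mm` and `step_mm`.
#' @export
build_roi_path <- function(azimuth, area, elevation = NULL, focus_rc,
                           pixel_pitch, roi_radius = 0.1, step = 0.15,
                           elev_tol = 5) {
  if (area[focus_rc[1], focus_rc[2]] != 1L)
    stop("focus must lie inside V1", call. = FALSE)
  sm <- median3(azimuth)
  nr <- nrow(sm); nc <- ncol(sm)
  step_px <- step / pixel_pitch
  fel <- if (!is.null(elevation)) elevation[focus_rc[1], focus_rc[2]] else 0

  grad_at <- function(rc) {
    r <- round(rc[1]); c <- round(rc[2])
    r0 <- max(1, r - 1); r1 <- min(nr, r + 1)
    c0 <- max(1, c - 1); c1 <- min(nc, c + 1)
    gx <- (sm[r, c1] - sm[r, c0]) / (c1 - c0)
    gy <- (sm[r1, c] - sm[r0, c]) / (r1 - r0)
    c(gy, gx)
  }
  march <- function(sgn) {
    pos <- as.numeric(focus_rc)
    pts <- list(pos)
    for (k in 1:200) {
      g <- grad_at(pos)
      ## inside LM the gradient flips sign (mirror); keep heading outward
      here <- area[round(pos[1]), round(pos[2])]
      dirsgn <- if (here == 2L) -sgn else sgn
      nrm <- sqrt(sum(g^2))
      if (nrm < 1e-9) break
      cand <- pos + dirsgn * g / nrm * step_px
      ## elevation iso-band correction: nudge the row back towards the band
      if (!is.null(elevation)) {
        rr <- max(1, min(nr, round(cand[1])))
        cc <- max(1, min(nc, round(cand[2])))
        if (abs(elevation[rr, cc] - fel) > elev_tol) {
          for (dr in c(-1, 1, -2, 2, -3, 3)) {
            r2 <- max(1, min(nr, round(cand[1]) + dr))
            if (abs(elevation[r2, cc] - fel) <= elev_tol) {
              cand[1] <- r2; break
            }
          }
        }
      }
      if (cand[1] < 1 || cand[1] > nr || cand[2] < 1 || cand[2] > nc) break
      if (area[round(cand[1]), round(cand[2])] == 0L) break
      pts[[length(pts) + 1]] <- cand
      pos <- cand
    }
    pts
  }
  for (sgn in c(1, -1)) {
    pts <- march(sgn)
    areas <- vapply(pts, function(p) area[round(p[1]), round(p[2])],
                    integer(1))
    if (any(areas == 2L)) {
      M <- do.call(rbind, pts)
      dists <- c(0, cumsum(sqrt(rowSums(diff(M)^2)))) * pixel_pitch
      df <- data.frame(row = round(M[, 1]), col = round(M[, 2]),
                       distance_mm = dists,
                       azimuth_deg = sm[cbind(round(M[, 1]), round(M[, 2]))],
                       area = areas)
      return(structure(df, class = c("roi_path", "data.frame"),
                       roi_radius_mm = roi_radius, step_mm = step))
    }
  }
  stop(sprintf(
    "path could not reach LM within the elevation band (last point row %d col %d)",
    round(pts[[length(pts)]][1]), round(pts[[length(pts)]][2])), call. = FALSE)
}

## data.frame subsetting keeps the roi_path attributes we need
#' @export
`[.roi_path` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "roi_radius_mm") <- attr(x, "roi_radius_mm")
    attr(out, "step_mm") <- attr(x, "step_mm")
    class(out) <- class(x)
  }
  out
}

#' @export
print.roi_path <- function(x, ...) {
  cat(sprintf(
    "<roi_path> %d ROIs (radius %.2f mm, step %.2f mm), %.2f mm total, %d in LM\n",
    nrow(x), attr(x, "roi_radius_mm"), attr(x, "step_mm"),
    max(x$distance_mm), sum(x$area == 2L)))
  invisible(x)
}
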