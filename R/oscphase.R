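## Hilbert-phase analysis of 6-11 Hz ictal oscillations: analytic movies,
## focus-referenced phase-delay maps, cycle averages, spatial phase variance
## and spiral (pinwheel) detection.

## analytic signal via FFT: x + i * Hilbert(x), columns of a matrix or a vector
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  F <- stats::mvfft(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(F * h, inverse = TRUE) / n
  if (vec) drop(A) else A
}

#' Band-passed analytic representation of a movie
#'
#' Each pixel trace is band-pass filtered (4th-order Butterworth applied
#' forward-backward, so zero phase) and converted to its analytic signal
#' f + i H(f) = A exp(i phi); the instantaneous amplitude A and wrapped phase
#' phi are returned per pixel-frame. Pixels with zero (or NA) traces get zero
#' amplitude and NA phase.
#'
#' @param dff a [dff_movie()] segment, at least 10 band periods long.
#' @param band numeric (low, high) in Hz, default c(6, 11).
#' @return object of class `analytic_movie`: `amplitude` and `phase` (frames x
#'   rows x cols arrays), `band`, `frame_times`, `mask`, `pixel_pitch`.
#' @export
analytic_movie <- function(dff, band = c(6, 11)) {
  stopifnot(inherits(dff, "iw_movie"))
  fr <- frame_rate(dff)
  if (fr <= 2 * band[2])
    stop("frame rate must exceed twice the band's high edge", call. = FALSE)
  if (diff(range(dff$frame_times)) < 10 / band[1])
    stop("segment must span at least 10 band periods", call. = FALSE)
  X <- movie_matrix(dff)
  X[is.na(X)] <- 0
  bf <- signal::butter(4, band / (fr / 2), type = "pass")
  flat <- vapply(seq_len(ncol(X)), function(j) {
    if (all(X[, j] == 0)) X[, j] else signal::filtfilt(bf, X[, j])
  }, numeric(nrow(X)))
  A <- analytic_signal(flat)
  amp <- Mod(A); ph <- Arg(A)
  ph[amp < 1e-12] <- NA_real_
  d <- dim(dff$frames)
  structure(list(amplitude = array(amp, d), phase = array(ph, d),
                 band = band, frame_times = dff$frame_times,
                 mask = dff$mask, pixel_pitch = dff$pixel_pitch),
            class = "analytic_movie")
}

#' @export
print.analytic_movie <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("<analytic_movie> %d frames of %d x %d px, band %.1f-%.1f Hz\n",
              d[1], d[2], d[3], x$band[1], x$band[2]))
  invisible(x)
}

## phase unwrapping (cumulative, vector)
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Focus-referenced phase-delay map
#'
#' Per pixel and frame the wrapped phase difference with the focus is taken;
#' the circular mean across the epoch is converted to time by dividing by the
#' mean instantaneous angular frequency of the focus (not a nominal band
#' centre, since the frequency drifts within seizures). Lags lie in
#' (-T/2, T/2] for the focus period T; a lag of exactly half a period maps to
#' +T/2. Pixels whose mean amplitude is below `amp_floor` times the focus
#' mean amplitude are excluded.
#'
#' @param am an `analytic_movie`.
#' @param focus_rc focus (row, col).
#' @param epoch numeric (t0, t1); default the whole segment.
#' @param amp_floor relative amplitude floor, default 0.05.
#' @return object of class `phase_delay_map`: `lag_s` (matrix, 0 at the
#'   focus), `circ_sd` (circular SD in radians), `n_frames`,
#'   `focus_freq_hz`.
#' @export
phase_delay_map <- function(am, focus_rc, epoch = NULL, amp_floor = 0.05) {
  stopifnot(inherits(am, "analytic_movie"))
  epoch <- epoch %||% range(am$frame_times)
  idx <- which(am$frame_times >= epoch[1] & am$frame_times <= epoch[2])
  if (length(idx) < 3) stop("epoch too short", call. = FALSE)
  d <- dim(am$amplitude)
  P <- matrix(am$phase, d[1], d[2] * d[3])[idx, , drop = FALSE]
  A <- matrix(am$amplitude, d[1], d[2] * d[3])[idx, , drop = FALSE]
  fpix <- (focus_rc[2] - 1) * d[2] + focus_rc[1]
  phf <- P[, fpix]
  if (any(!is.finite(phf)))
    stop("focus phase undefined within the epoch", call. = FALSE)
  fr <- 1 / stats::median(diff(am$frame_times))
  omega <- mean(diff(unwrap_phase(phf))) * fr
  if (omega <= 0) stop("focus instantaneous frequency not positive",
                       call. = FALSE)
  dphi <- sweep(P, 1, phf, "-")
  z <- colMeans(exp(1i * dphi))
  ## a pixel lagging the focus has a negative phase difference; report it as a
  ## positive time lag (matching the delay-map convention)
  mean_dphi <- wrap_pi(-Arg(z))
  circ_sd <- sqrt(-2 * log(pmin(1, Mod(z))))
  lag <- mean_dphi / omega
  ok <- colMeans(A) >= amp_floor * mean(A[, fpix]) &
    as.vector(am$mask) & is.finite(mean_dphi)
  lag[!ok] <- NA_real_
  circ_sd[!ok] <- NA_real_
  structure(list(lag_s = matrix(lag, d[2], d[3]),
                 circ_sd = matrix(circ_sd, d[2], d[3]),
                 n_frames = length(idx),
                 focus_freq_hz = omega / (2 * pi)),
            class = "phase_delay_map")
}

#' @export
print.phase_delay_map <- function(x, ...) {
  cat(sprintf(
    "<phase_delay_map> focus frequency %.2f Hz | lag range [%.1f, %.1f] ms over %d frames\n",
    x$focus_freq_hz, 1000 * min(x$lag_s, na.rm = TRUE),
    1000 * max(x$lag_s, na.rm = TRUE), x$n_frames))
  invisible(x)
}

#' Cycle average of an oscillation
#'
#' Cuts a trace into cycles at the -pi crossings of a reference phase,
#' resamples each cycle to a common length and averages. Requires at least 3
#' complete cycles. The average preserves non-sinusoidal shape.
#'
#' @param x numeric trace (e.g. unfiltered LFP or fluorescence).
#' @param ref_phase wrapped reference phase, same length as `x` (e.g. the
#'   focus phase of an [analytic_movie()] or of a filtered LFP).
#' @param n_points samples per cycle in the output, default 100.
#' @return list with `phase` (cycle axis, -pi..pi), `mean`, `sd`, `n_cycles`.
#' @export
cycle_average <- function(x, ref_phase, n_points = 100) {
  if (length(x) != length(ref_phase))
    stop("trace and reference phase must have equal length", call. = FALSE)
  ## cycle boundaries: wrap-around points of the reference phase
  wraps <- which(diff(ref_phase) < -pi)
  if (length(wraps) < 4)
    stop("need at least 3 complete cycles", call. = FALSE)
  cycles <- lapply(seq_len(length(wraps) - 1), function(k) {
    seg <- x[(wraps[k] + 1):wraps[k + 1]]
    stats::approx(seq_along(seg), seg, n = n_points)$y
  })
  M <- do.call(rbind, cycles)
  list(phase = seq(-pi, pi, length.out = n_points),
       mean = colMeans(M),
       sd = apply(M, 2, stats::sd),
       n_cycles = nrow(M))
}

#' Spatial circular variance of the phase field
#'
#' 1 - |mean resultant vector| of the pixel phases in one frame: 0 for a
#' uniform phase field, approaching 1 when phases cover the circle (e.g.
#' during spiral waves).
#'
#' @param am an `analytic_movie`.
#' @param frame frame index.
#' @param amplitude_weighted weight pixels by amplitude; default FALSE.
#' @return circular variance in [0, 1].
#' @export
spatial_phase_variance <- function(am, frame, amplitude_weighted = FALSE) {
  stopifnot(inherits(am, "analytic_movie"))
  ph <- am$phase[frame, , ][am$mask]
  w <- if (amplitude_weighted) am$amplitude[frame, , ][am$mask] else
    rep(1, length(ph))
  ok <- is.finite(ph)
  if (sum(ok) < 10) stop("fewer than 10 valid pixels", call. = FALSE)
  z <- sum(w[ok] * exp(1i * ph[ok])) / sum(w[ok])
  1 - Mod(z)
}

#' Detect pinwheels (phase singularities) in a phase frame
#'
#' Computes the winding number around every elementary 2x2 pixel loop as the
#' sum of wrapped phase differences divided by 2 pi; loops with winding +/-1
#' are phase singularities (spiral cores). For each, the local amplitude and
#' whether it is a local amplitude minimum within its 3x3 neighbourhood are
#' reported.
#'
#' @param am an `analytic_movie`.
#' @param frame frame index.
#' @return data.frame with row, col (top-left corner of the loop, i.e. the
#'   core lies within the plaquette), winding, core_amplitude,
#'   is_amp_minimum. Zero rows when the field has no singularities.
#' @export
detect_pinwheels <- function(am, frame) {
  stopifnot(inherits(am, "analytic_movie"))
  ph <- am$phase[frame, , ]
  A <- am$amplitude[frame, , ]
  w <- plaquette_winding(ph)
  hits <- which(abs(w) == 1L, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(row = integer(0), col = integer(0), winding = integer(0),
                      core_amplitude = numeric(0), is_amp_minimum = logical(0)))
  nr <- nrow(ph); nc <- ncol(ph)
  out <- data.frame(row = hits[, 1], col = hits[, 2],
                    winding = w[hits])
  out$core_amplitude <- vapply(seq_len(nrow(out)), function(i) {
    r <- out$row[i]; c <- out$col[i]
    mean(A[r:(r + 1), c:(c + 1)])
  }, numeric(1))
  out$is_amp_minimum <- vapply(seq_len(nrow(out)), function(i) {
    r <- out$row[i]; c <- out$col[i]
    r0 <- max(1, r - 1); r1 <- min(nr, r + 2)
    c0 <- max(1, c - 1); c1 <- min(nc, c + 2)
    out$core_amplitude[i] <= min(A[r0:r1, c0:c1]) + 1e-12
  }, logical(1))
  out
}

## winding number of every elementary pixel loop; (nr-1) x (nc-1) matrix
plaquette_winding <- function(ph) {
  nr <- nrow(ph); nc <- ncol(ph)
  p00 <- ph[-nr, -nc]; p01 <- ph[-nr, -1]
  p11 <- ph[-1, -1];  p10 <- ph[-1, -nc]
  s <- wrap_pi(p01 - p00) + wrap_pi(p11 - p01) +
    wrap_pi(p10 - p11) + wrap_pi(p00 - p10)
  w <- round(s / (2 * pi))
  w[!is.finite(w)] <- 0L
  w
}

#' Total winding number along the boundary of a phase field
#'
#' Sum of wrapped phase differences along the outer boundary, divided by 2 pi.
#' Equals the sum of interior pinwheel charges (topological charge
#' conservation), which is the consistency check used in the tests.
#'
#' @param ph phase matrix.
#' @return integer winding number.
#' @export
boundary_winding <- function(ph) {
  nr <- nrow(ph); nc <- ncol(ph)
  loop <- c(ph[1, 1:nc], ph[2:nr, nc], ph[nr, (nc - 1):1], ph[(nr - 1):1, 1])
  round(sum(wrap_pi(diff(loop))) / (2 * pi))
}

#' Pacemaker epoch of a seizure
#'
#' Duration of the initial run of oscillation cycles in which the focus leads,
#' i.e. lies within the earliest 5% of pixel phases. Leadership is evaluated
#' per cycle of the focus oscillation (median across the cycle's frames, over
#' pixels whose instantaneous amplitude reaches `amp_floor` of the frame
#' maximum). Cycles before the oscillation is established at the focus -
#' where the band-pass filter responds to the invasion step rather than to the
#' wave - are skipped, and the run starts at the first leading cycle.
#'
#' @param am an `analytic_movie`.
#' @param focus_rc focus (row, col).
#' @param quantile_lead leading fraction, default 0.05.
#' @param amp_floor relative amplitude floor for a pixel to enter the
#'   comparison, default 0.2.
#' @return duration in seconds of the initial pacemaker run (0 if the focus
#'   never leads).
#' @export
pacemaker_epoch <- function(am, focus_rc, quantile_lead = 0.05,
                            amp_floor = 0.2) {
  d <- dim(am$amplitude)
  P <- matrix(am$phase, d[1], d[2] * d[3])
  A <- matrix(am$amplitude, d[1], d[2] * d[3])
  fpix <- (focus_rc[2] - 1) * d[2] + focus_rc[1]
  msk <- as.vector(am$mask)
  ## cycle boundaries from the focus phase wrap-arounds
  phf <- P[, fpix]
  wraps <- which(diff(phf) < -pi)
  if (length(wraps) < 2) return(0)
  bounds <- c(1, wraps, d[1])
  cyc_lead <- vapply(seq_len(length(bounds) - 1), function(k) {
    ts <- bounds[k]:bounds[k + 1]
    ## pixels must have been oscillating for at least one full cycle already:
    ## a pixel the front is just invading carries the filter's step response,
    ## whose phase says nothing about wave timing
    lag <- max(1L, ts[1] - (ts[length(ts)] - ts[1]))
    stationary <- A[lag, msk] >= 0.5 * A[ts[1], msk]
    f <- vapply(ts, function(t) {
      dphi <- wrap_pi(P[t, msk] - P[t, fpix])
      ok <- is.finite(dphi) & stationary &
        A[t, msk] >= amp_floor * max(A[t, msk])
      if (sum(ok) < 10) return(NA_real_)
      mean(dphi[ok] > 0)
    }, numeric(1))
    if (all(is.na(f))) NA else stats::median(f, na.rm = TRUE) <= quantile_lead
  }, logical(1))
  first <- which(cyc_lead)[1]
  if (is.na(first)) return(0)
  last <- first
  while (last < length(cyc_lead) && isTRUE(cyc_lead[last + 1])) last <- last + 1
  am$frame_times[bounds[last + 1]] - am$frame_times[bounds[first]]
}
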