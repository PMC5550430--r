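## Synthetic epileptiform activity: event scripts, movie / LFP / retinotopy
## renderers, all seed-deterministic with planted ground truth.

#' Default generator parameters
#'
#' Central record of the generator's defaults: event schedule (interictal rate
#' 13.4 per min, seizures 1.0 per min), lognormal duration medians (0.5 s and
#' 8.6 s), peak dF/F (1.25 interictal, 1.75 seizure), the interictal footprint
#' (isotropic homotopy kernel of 25 deg in azimuth and elevation, contiguity
#' half-width 0.9 mm, floor = peak / V1-LM amplitude ratio of 8), the seizure
#' delay field (front speed 0.48 mm/s, homotopic jump 4 s, retinotopic
#' slowdown 0.008 s/deg), ictal oscillations (6-11 Hz,
#' relative amplitude 0.2, phase-lag slope 0.002 s per s of invasion delay) and
#' noise (5% of event peak per pixel-frame).
#'
#' @return named list of defaults.
#' @export
generator_defaults <- function() {
  list(
    interictal_rate_per_min = 13.4, seizure_rate_per_min = 1.0,
    interictal_median_s = 0.5, seizure_median_s = 8.6,
    interictal_sdlog = 0.3, seizure_sdlog = 0.15,
    interictal_peak = 1.25, seizure_peak = 1.75,
    homotopy_width_deg = 25, contiguity_hwhm_mm = 0.9,
    elevation_width_deg = 25,
    v1_lm_ratio = 8, rise_s = 0.05, decay_s = 0.3,
    front_speed_mm_s = 0.48, jump_delay_s = 4.0,
    retinotopic_slowdown_s_deg = 0.008,
    osc_band_hz = c(6, 11), osc_rel_amp = 0.2, osc_lag_slope = 0.002,
    sigmoid_tau_s = 0.12, noise_frac_of_peak = 0.05,
    focus_jitter_sd_mm = 0.32 / sqrt(2),
    lfp_noise_sd_mv = 0.05, interictal_amp_mv = 1.2, seizure_amp_mv = 1.0,
    deflection_width_ms = 75
  )
}

#' Build a schedule of epileptiform events
#'
#' Draws a non-overlapping schedule of interictal events and seizures over a
#' recording of given length. Onsets follow Poisson processes at the two class
#' rates (candidates that would overlap an already placed event are dropped),
#' durations are lognormal with the class medians, and each seizure receives an
#' oscillation frequency drawn uniformly within the 6-11 Hz band.
#'
#' @param duration_min recording length in minutes.
#' @param seed integer seed; the schedule is fully reproducible.
#' @param defaults parameter list, see [generator_defaults()].
#' @return an `event_script`: data.frame with columns class, onset_s,
#'   duration_s, peak_dff, osc_freq_hz plus the delay-field parameters.
#' @export
make_event_script <- function(duration_min = 30, seed = 1,
                              defaults = generator_defaults()) {
  p <- defaults
  set.seed(seed)
  total_s <- duration_min * 60
  draw_onsets <- function(rate_per_min) {
    n <- stats::rpois(1, rate_per_min * duration_min * 1.2)
    sort(stats::runif(n, 0, total_s))
  }
  sz_on <- draw_onsets(p$seizure_rate_per_min)
  sz_dur <- stats::rlnorm(length(sz_on), log(p$seizure_median_s), p$seizure_sdlog)
  keep <- rep(TRUE, length(sz_on)); last_end <- -Inf
  for (i in seq_along(sz_on)) {
    if (sz_on[i] < last_end + 2 || sz_on[i] + sz_dur[i] > total_s)
      keep[i] <- FALSE
    else last_end <- sz_on[i] + sz_dur[i]
  }
  sz_on <- sz_on[keep]; sz_dur <- sz_dur[keep]
  ## trim back to the nominal rate (overdrawn above to survive pruning)
  n_target <- round(p$seizure_rate_per_min * duration_min)
  if (length(sz_on) > n_target) {
    sz_on <- sz_on[seq_len(n_target)]; sz_dur <- sz_dur[seq_len(n_target)]
  }

  ii_on <- draw_onsets(p$interictal_rate_per_min)
  ii_dur <- stats::rlnorm(length(ii_on), log(p$interictal_median_s),
                          p$interictal_sdlog)
  busy <- cbind(sz_on - 1, sz_on + sz_dur + 1)
  keep <- rep(TRUE, length(ii_on)); last_end <- -Inf
  for (i in seq_along(ii_on)) {
    t0 <- ii_on[i]; t1 <- t0 + ii_dur[i]
    in_sz <- nrow(busy) > 0 && any(t1 > busy[, 1] & t0 < busy[, 2])
    if (in_sz || t0 < last_end + 0.8 || t1 > total_s) keep[i] <- FALSE
    else last_end <- t1
  }
  ii_on <- ii_on[keep]; ii_dur <- ii_dur[keep]

  sz_df <- if (length(sz_on))
    data.frame(class = "seizure", onset_s = sz_on,
               duration_s = sz_dur, peak_dff = p$seizure_peak,
               osc_freq_hz = stats::runif(length(sz_on), p$osc_band_hz[1],
                                          p$osc_band_hz[2]))
  ii_df <- if (length(ii_on))
    data.frame(class = "interictal", onset_s = ii_on,
               duration_s = ii_dur, peak_dff = p$interictal_peak,
               osc_freq_hz = NA_real_)
  df <- rbind(sz_df, ii_df)
  if (is.null(df))
    df <- data.frame(class = character(0), onset_s = numeric(0),
                     duration_s = numeric(0), peak_dff = numeric(0),
                     osc_freq_hz = numeric(0))
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  df$speed_mm_s <- p$front_speed_mm_s
  df$jump_delay_s <- p$jump_delay_s
  df$homotopy_width_deg <- p$homotopy_width_deg
  df$retinotopic_slowdown_s_deg <- p$retinotopic_slowdown_s_deg
  df$osc_lag_slope <- p$osc_lag_slope
  structure(df, class = c("event_script", "data.frame"), defaults = p,
            duration_s = total_s, seed = seed)
}

#' Script for a single epileptiform event
#'
#' Convenience builder for a one-event script, used when rendering individual
#' interictal events or seizures (the common case in simulation studies).
#'
#' @param class "interictal" or "seizure".
#' @param onset_s onset time in seconds.
#' @param duration_s event duration; defaults to the class median.
#' @param peak_dff peak dF/F; defaults to the class peak.
#' @param osc_freq_hz seizure oscillation frequency in Hz.
#' @param homotopic enable the homotopic route of the seizure delay field.
#' @param swave_onset include the brief standing wave at seizure onset.
#' @param defaults parameter list, see [generator_defaults()].
#' @return a one-row `event_script`.
#' @export
single_event_script <- function(class = "interictal", onset_s = 0,
                                duration_s = NULL, peak_dff = NULL,
                                osc_freq_hz = 8, homotopic = TRUE,
                                swave_onset = TRUE,
                                defaults = generator_defaults()) {
  p <- defaults
  duration_s <- duration_s %||%
    if (class == "seizure") p$seizure_median_s else p$interictal_median_s
  peak_dff <- peak_dff %||%
    if (class == "seizure") p$seizure_peak else p$interictal_peak
  df <- data.frame(class = class, onset_s = onset_s, duration_s = duration_s,
                   peak_dff = peak_dff,
                   osc_freq_hz = if (class == "seizure") osc_freq_hz else NA,
                   speed_mm_s = p$front_speed_mm_s,
                   jump_delay_s = p$jump_delay_s,
                   homotopy_width_deg = p$homotopy_width_deg,
                   retinotopic_slowdown_s_deg = p$retinotopic_slowdown_s_deg,
                   osc_lag_slope = p$osc_lag_slope, homotopic = homotopic,
                   swave_onset = swave_onset)
  structure(df, class = c("event_script", "data.frame"), defaults = p,
            duration_s = onset_s + duration_s, seed = NA)
}

## interictal spatial footprint: contiguity x homotopy around a centre pixel.
## The floor of the contiguity term carries the homotopic lobe: at the LM
## pixel homotopic to the centre the map equals b = peak / v1_lm_ratio, which
## sets the V1/LM amplitude ratio. An elevation tuning factor keeps the
## homotopic lobe compact instead of an iso-azimuth stripe; along the
## iso-elevation ROI path it is constant, so the path profile is exactly
## C(x) * H(R(x)).
interictal_map <- function(geom, center_rc, peak, defaults) {
  p <- defaults
  d <- dist_from(geom$grid_shape, geom$pixel_pitch, center_rc)
  b <- peak / p$v1_lm_ratio
  C <- contiguity_term(d, lambda = p$contiguity_hwhm_mm, a = peak,
                       b = b, x_focus = 0)
  center_az <- geom$azimuth[center_rc[1], center_rc[2]]
  H <- homotopy_term(geom$azimuth, sigma = p$homotopy_width_deg,
                     R_focus = center_az)
  center_el <- geom$elevation[center_rc[1], center_rc[2]]
  Hel <- homotopy_term(geom$elevation, sigma = p$elevation_width_deg,
                       R_focus = center_el)
  m <- C * H * Hel
  m[geom$area == 0L] <- 0
  m
}

## normalised difference-of-exponentials time course (peak 1)
interictal_timecourse <- function(t_rel, rise, decay) {
  tc <- ifelse(t_rel < 0, 0, exp(-t_rel / decay) - exp(-t_rel / rise))
  tstar <- rise * decay / (decay - rise) * log(decay / rise)
  tc / (exp(-tstar / decay) - exp(-tstar / rise))
}

#' Render a dF/F movie of scripted epileptiform events
#'
#' Interictal events are exact standing waves before noise: one spatial map
#' (the multiplicative contiguity-by-homotopy footprint, with the LM lobe
#' attenuated by the V1/LM amplitude ratio) times one difference-of-exponentials
#' time course. Seizures are travelling fronts: each pixel follows a sigmoidal
#' onset at its planted delay-to-invasion (see [plant_delay_field()]), carries
#' a 6-11 Hz oscillation whose phase lag grows in proportion to that delay, and
#' decays after the scripted offset. I.i.d. Gaussian noise is added per
#' pixel-frame.
#'
#' @param geom a `cortex_geometry`.
#' @param script an `event_script` (typically one or a few events).
#' @param frame_rate frames per second, >= 20.
#' @param noise_sd noise SD in dF/F units; default 5% of the largest scripted
#'   peak. Use 0 for noiseless ground truth.
#' @param duration_s movie length in seconds; defaults to the script end plus a
#'   short tail. Events extending past the end are truncated with a warning
#'   recorded in the ground truth.
#' @param jitter_focus logical; jitter interictal event centres around the
#'   focus (SD `focus_jitter_sd_mm` per axis). Seizures always originate at the
#'   focus.
#' @param seed integer seed.
#' @return a [dff_movie()] with attribute `ground_truth`: per-event centres,
#'   planted maps / delay fields, oscillation parameters, noise SD and
#'   truncation flags.
#' @export
render_event_movie <- function(geom, script, frame_rate = 35, noise_sd = NULL,
                               duration_s = NULL, jitter_focus = TRUE,
                               seed = 1) {
  stopifnot(inherits(geom, "cortex_geometry"))
  if (frame_rate < 20) stop("frame_rate must be at least 20 Hz", call. = FALSE)
  p <- attr(script, "defaults") %||% generator_defaults()
  if (is.null(noise_sd)) noise_sd <- p$noise_frac_of_peak * max(script$peak_dff)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  duration_s <- duration_s %||% (max(script$onset_s + script$duration_s) + 0.2)
  set.seed(seed)
  nt <- max(2L, floor(duration_s * frame_rate))
  times <- (seq_len(nt) - 1) / frame_rate
  nr <- geom$grid_shape[1]; nc <- geom$grid_shape[2]
  X <- matrix(0, nt, nr * nc)
  gt <- list(events = list(), noise_sd = noise_sd, frame_rate = frame_rate)

  for (i in seq_len(nrow(script))) {
    ev <- script[i, ]
    truncated <- ev$onset_s + ev$duration_s > duration_s + 1e-9
    if (truncated)
      warning(sprintf("event %d extends past the movie end; truncated", i),
              call. = FALSE)
    if (ev$class == "interictal") {
      center <- geom$focus_rc
      if (jitter_focus) {
        jit <- stats::rnorm(2, 0, p$focus_jitter_sd_mm / geom$pixel_pitch)
        center <- pmax(c(1, 1), pmin(geom$grid_shape, round(center + jit)))
        if (geom$area[center[1], center[2]] != 1L) center <- geom$focus_rc
      }
      map <- interictal_map(geom, center, ev$peak_dff, p)
      tc <- interictal_timecourse(times - ev$onset_s, p$rise_s, p$decay_s)
      X <- X + tc %o% as.vector(map)
      gt$events[[i]] <- list(class = "interictal", center_rc = center,
                             map = map, onset_s = ev$onset_s,
                             duration_s = ev$duration_s, truncated = truncated)
    } else {
      delay <- plant_delay_field(geom, speed = ev$speed_mm_s,
                                 jump_delay = ev$jump_delay_s,
                                 homotopy_width = ev$homotopy_width_deg,
                                 retinotopic_slowdown = ev$retinotopic_slowdown_s_deg,
                                 homotopic = if (is.null(ev$homotopic)) TRUE
                                             else ev$homotopic)
      dvec <- as.vector(delay); dvec[is.na(dvec)] <- 0
      tau <- p$sigmoid_tau_s
      t_rel <- times - ev$onset_s
      ## rising sigmoid gated by the event, exponential release after offset;
      ## midpoint placed so the 60%-of-plateau crossing falls exactly at the
      ## planted delay (logit(0.6) = 0.4055)
      S <- 1 / (1 + exp(-(outer(t_rel, dvec, "-") + 0.4054651 * tau) / tau))
      off <- t_rel > ev$duration_s
      if (any(off))
        S[off, ] <- S[off, ] * exp(-(t_rel[off] - ev$duration_s) / 0.5)
      gate <- t_rel >= 0
      S <- S * gate
      osc <- sin(2 * pi * ev$osc_freq_hz *
                   outer(t_rel, ev$osc_lag_slope * dvec, "-"))
      sig <- ev$peak_dff * S * (1 + p$osc_rel_amp * osc)
      ## seizures begin like interictal events: a brief standing wave over
      ## the interictal footprint precedes the propagating front
      if (is.null(ev$swave_onset) || isTRUE(ev$swave_onset)) {
        swave_map <- interictal_map(geom, geom$focus_rc, p$interictal_peak, p)
        swave_tc <- interictal_timecourse(t_rel, p$rise_s, p$decay_s)
        sig <- sig + swave_tc %o% as.vector(swave_map)
      }
      sig[, as.vector(geom$area) == 0L] <- 0
      X <- X + sig
      gt$events[[i]] <- list(class = "seizure", center_rc = geom$focus_rc,
                             delay_field = delay, onset_s = ev$onset_s,
                             duration_s = ev$duration_s,
                             osc_freq_hz = ev$osc_freq_hz,
                             osc_lag_slope = ev$osc_lag_slope,
                             truncated = truncated)
    }
  }
  if (noise_sd > 0) X <- X + stats::rnorm(length(X), 0, noise_sd)
  mov <- dff_movie(array(X, c(nt, nr, nc)), times, geom$pixel_pitch,
                   mask = geometry_mask(geom))
  attr(mov, "ground_truth") <- gt
  mov
}

#' Render a synthetic LFP trace coupled to the scripted events
#'
#' Each event opens with a sharp negative deflection (default width 75 ms);
#' seizures additionally carry a sustained negative slow envelope for their
#' scripted duration plus a 6-11 Hz oscillation riding on it. Gaussian
#' background noise is added throughout.
#'
#' @param script an `event_script`.
#' @param lfp_rate sample rate in Hz, >= 500.
#' @param duration_s trace length in seconds; defaults to the script span.
#' @param seed integer seed.
#' @return an [lfp_trace()] with attribute `ground_truth` (planted onsets,
#'   offsets and classes).
#' @export
render_lfp <- function(script, lfp_rate = 1000, duration_s = NULL, seed = 1) {
  if (lfp_rate < 500) stop("lfp_rate must be at least 500 Hz", call. = FALSE)
  p <- attr(script, "defaults") %||% generator_defaults()
  duration_s <- duration_s %||% attr(script, "duration_s") %||%
    (max(script$onset_s + script$duration_s) + 2)
  set.seed(seed)
  n <- floor(duration_s * lfp_rate)
  tt <- (seq_len(n) - 1) / lfp_rate
  v <- stats::rnorm(n, 0, p$lfp_noise_sd_mv)
  w_sd <- p$deflection_width_ms / 1000 / 4   # deflection ~ 4 sd wide
  for (i in seq_len(nrow(script))) {
    ev <- script[i, ]
    t0 <- ev$onset_s
    idx <- which(tt >= t0 - 0.2 & tt <= t0 + ev$duration_s + 2)
    if (!length(idx)) next
    tr <- tt[idx] - t0
    amp <- if (ev$class == "seizure") p$seizure_amp_mv else p$interictal_amp_mv
    spike <- -amp * exp(-(tr - 2 * w_sd)^2 / (2 * w_sd^2))
    ## slow component sustaining the event: trapezoid over the scripted
    ## duration with the ramps inside. For seizures the electrographic
    ## discharge ends slightly before the scripted (fluorescence) offset;
    ## the 0.8 s trim also compensates the slow tail of the analytic
    ## envelope used by the offset detector.
    ramp <- 0.15
    trim <- if (ev$class == "seizure") 0.8 else 0
    env_len <- max(ev$duration_s - trim, 2 * ramp)
    slow <- -0.6 * amp *
      pmax(0, pmin(1, pmin(tr / ramp, (env_len - tr) / ramp)))
    osc <- 0
    if (ev$class == "seizure")
      osc <- 0.5 * amp * (slow / (0.6 * amp)) *
        -sin(2 * pi * ev$osc_freq_hz * tr)
    v[idx] <- v[idx] + spike + slow + osc
  }
  out <- lfp_trace(v, lfp_rate)
  attr(out, "ground_truth") <- data.frame(
    onset_s = script$onset_s, offset_s = script$onset_s + script$duration_s,
    class = script$class)
  out
}

#' Render a retinotopic-mapping session
#'
#' Contrast-reversing gratings at a set of azimuthal positions drive each pixel
#' at twice the reversal frequency, with an amplitude given by a Gaussian
#' position-tuning curve centred on the pixel's preferred azimuth.
#'
#' @param geom a `cortex_geometry`.
#' @param stim_azimuths stimulus centres in degrees (>= 2 positions; default 4
#'   positions spanning the stimulus range).
#' @param reversal_rate grating reversal rate in Hz (responses at twice this).
#' @param stim_duration_s stimulus epoch length, default 5 s.
#' @param frame_rate imaging rate, default 50 Hz.
#' @param response_amp peak visual response in dF/F, default 0.04.
#' @param tuning_sigma true tuning width in degrees, default 25.
#' @param noise_sd per pixel-frame noise SD, default 0 (noiseless).
#' @param seed integer seed.
#' @return list with `movies` (one [dff_movie()] per stimulus) and `stimuli`
#'   (data.frame of azimuths and parameters).
#' @export
render_retinotopy_session <- function(geom, stim_azimuths = NULL,
                                      reversal_rate = 2, stim_duration_s = 5,
                                      frame_rate = 50, response_amp = 0.04,
                                      tuning_sigma = 25, noise_sd = 0,
                                      seed = 1) {
  stopifnot(inherits(geom, "cortex_geometry"))
  span <- geom$azimuth_span
  stim_azimuths <- stim_azimuths %||%
    (span[1] + (span[2] - span[1]) * (seq_len(4) - 0.5) / 4)
  if (length(stim_azimuths) < 2)
    stop("at least 2 stimulus positions are required", call. = FALSE)
  set.seed(seed)
  nt <- floor(stim_duration_s * frame_rate)
  times <- (seq_len(nt) - 1) / frame_rate
  f2 <- 2 * reversal_rate
  movies <- lapply(stim_azimuths, function(sa) {
    amp <- response_amp *
      exp(-(geom$azimuth - sa)^2 / (2 * tuning_sigma^2))
    amp[geom$area == 0L] <- 0
    ## rectified response: oscillates at the second harmonic of the reversal
    X <- outer(0.5 * (1 - cos(2 * pi * f2 * times)), as.vector(amp))
    if (noise_sd > 0) X <- X + stats::rnorm(length(X), 0, noise_sd)
    dff_movie(array(X, c(nt, geom$grid_shape[1], geom$grid_shape[2])),
              times, geom$pixel_pitch, mask = geometry_mask(geom))
  })
  list(movies = movies,
       stimuli = data.frame(azimuth_deg = stim_azimuths,
                            reversal_rate_hz = reversal_rate,
                            duration_s = stim_duration_s,
                            frame_rate_hz = frame_rate),
       tuning_sigma = tuning_sigma, response_amp = response_amp)
}
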