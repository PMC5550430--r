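## Seeded simulation studies: generate synthetic data at the generator
## defaults, run the corresponding analysis end to end, and return the
## recovered quantities. These are the package's benchmark experiments; the
## test suite and scripts/acceptance.R call them directly.

#' Standing-wave recovery study
#'
#' Simulates interictal events as exact standing waves plus i.i.d. Gaussian
#' noise of `noise_frac` times the event peak, fits the rank-1 model per event
#' over the event window, and reports fit quality.
#'
#' @param n_events number of events, default 50.
#' @param noise_frac noise SD as a fraction of the event peak.
#' @param seed integer seed.
#' @param frame_rate imaging rate, default 35 Hz.
#' @return list with `ve` (per-event variance explained), `max_rms_residual`
#'   (largest per-frame RMS residual across all events, dF/F units).
#' @export
study_standing_wave <- function(n_events = 50, noise_frac = 0.05, seed = 1,
                                frame_rate = 35) {
  geom <- make_geometry()
  p <- generator_defaults()
  p$noise_frac_of_peak <- noise_frac
  ve <- numeric(n_events); max_rms <- 0
  for (i in seq_len(n_events)) {
    sc <- single_event_script("interictal", defaults = p)
    mov <- render_event_movie(geom, sc, frame_rate = frame_rate,
                              noise_sd = noise_frac * p$interictal_peak,
                              seed = seed * 1000 + i)
    fit <- fit_standing_wave(mov, window = c(0, sc$duration_s[1]))
    ve[i] <- fit$variance_explained
    max_rms <- max(max_rms, max(fit$rms_residual_series))
  }
  list(ve = ve, max_rms_residual = max_rms)
}

#' Profile-model recovery study
#'
#' Simulates interictal events with a planted homotopy width and contiguity
#' half-width, recovers the retinotopic map from a rendered mapping session,
#' builds the V1 -> LM ROI path, extracts per-event profiles and fits the
#' six-parameter multiplicative model.
#'
#' @param n_events number of events, default 30.
#' @param sigma planted homotopy width (deg), default 25.
#' @param lambda planted contiguity HWHM (mm), default 0.6.
#' @param noise_frac noise SD as a fraction of the event peak, default 0.05.
#' @param seed integer seed.
#' @return list with `sigma`, `lambda` (fitted per event) and `path`.
#' @export
study_profile_model <- function(n_events = 30, sigma = 25, lambda = 0.6,
                                noise_frac = 0.05, seed = 1) {
  geom <- make_geometry()
  p <- generator_defaults()
  p$homotopy_width_deg <- sigma
  p$contiguity_hwhm_mm <- lambda
  p$noise_frac_of_peak <- noise_frac
  session <- render_retinotopy_session(geom, seed = seed)
  rmap <- map_retinotopy(session)
  path <- build_roi_path(rmap$azimuth, geom$area, geom$elevation,
                         geom$focus_rc, geom$pixel_pitch)
  sig <- lam <- numeric(n_events)
  for (i in seq_len(n_events)) {
    sc <- single_event_script("interictal", defaults = p)
    mov <- render_event_movie(geom, sc,
                              noise_sd = noise_frac * p$interictal_peak,
                              jitter_focus = FALSE, seed = seed * 1000 + i)
    prof <- extract_profile(mov, path, c(0, sc$duration_s[1]))
    fit <- fit_profile_model(prof)
    sig[i] <- fit$par[["sigma"]]
    lam[i] <- fit$par[["lambda"]]
  }
  list(sigma = sig, lambda = lam, path = path)
}

#' Seizure-invasion recovery study
#'
#' Simulates seizures at the generator-default front speed, computes per-pixel
#' delay-to-invasion maps (60% of the pixel's own maximum, on pixels recruited
#' above 30% of the focus peak), averages them across seizures and runs the
#' binned delay-vs-distance regression with the retinotopic residual analysis.
#'
#' @param n_seizures number of seizures, default 20.
#' @param homotopic enable the generator's homotopic route, default TRUE.
#' @param seed integer seed.
#' @param frame_rate imaging rate, default 35 Hz.
#' @return the `speed_fit` (see [speed_regression()]), plus element
#'   `delay_maps`.
#' @export
study_invasion <- function(n_seizures = 20, homotopic = TRUE, seed = 1,
                           frame_rate = 35) {
  geom <- make_geometry()
  p <- generator_defaults()
  dur <- 8
  maps <- vector("list", n_seizures)
  for (i in seq_len(n_seizures)) {
    sc <- single_event_script("seizure", duration_s = dur,
                              homotopic = homotopic, defaults = p)
    mov <- render_event_movie(geom, sc, frame_rate = frame_rate,
                              duration_s = dur + 0.5,
                              seed = seed * 1000 + i)
    rec <- recruited_mask(mov, focus_peak = p$seizure_peak)
    maps[[i]] <- compute_delay_map(mov, onset_s = 0, recruited = rec)
  }
  fit <- speed_regression(maps, geom)
  fit$delay_maps <- maps
  fit
}

#' LFP detection and classification study
#'
#' Generates a synthetic session at the default event schedule, renders the
#' coupled LFP, detects and classifies events, and scores the result against
#' the planted ground truth.
#'
#' @param duration_min session length in minutes, default 30.
#' @param seed integer seed.
#' @param match_s onset matching tolerance in seconds, default 0.25.
#' @return list with `events` (classified table), `ground_truth`,
#'   `seizure_median_s`, `interictal_median_s`, `precision`, `recall`.
#' @export
study_lfp_detection <- function(duration_min = 30, seed = 1, match_s = 0.25) {
  script <- make_event_script(duration_min = duration_min, seed = seed)
  lfp <- render_lfp(script, seed = seed + 1)
  ev <- suppressWarnings(classify_events(detect_events(lfp)))
  gt <- attr(lfp, "ground_truth")
  precision <- mean(vapply(ev$onset_s,
                           function(o) min(abs(gt$onset_s - o)) < match_s,
                           logical(1)))
  recall <- mean(vapply(gt$onset_s,
                        function(o) any(abs(ev$onset_s - o) < match_s),
                        logical(1)))
  list(events = ev, ground_truth = gt,
       seizure_median_s = stats::median(
         ev$duration_s[ev$class == "seizure"]),
       interictal_median_s = stats::median(
         ev$duration_s[ev$class == "interictal"]),
       precision = precision, recall = recall)
}
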