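## End-to-end orchestration: validated configuration with every analysis
## threshold in one place, and a seeded simulate -> detect -> fit -> report run.

#' Default pipeline configuration
#'
#' Every threshold used by the analyses appears here with its default and can
#' be overridden: the dF/F baseline percentile (0.20), the LFP derivative
#' threshold (3 SD), the focus-localisation threshold (60% of class peak) and
#' window (500 ms), the recruitment threshold (30% of focus peak), the
#' delay-to-invasion threshold (60% of the pixel maximum), the ictal
#' oscillation band (6-11 Hz), the minimum imaged seizure extent (6 s) and the
#' generator defaults of [generator_defaults()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    dff = list(baseline_percentile = 0.20),
    lfp = list(threshold_sd = 3, refractory_s = 0.3, sustain_s = 0.2,
               resample_hz = 100, fallback_duration_s = 2),
    focus = list(threshold = 0.60, early_s = 0.5),
    invasion = list(recruit_threshold = 0.30, delay_threshold = 0.60,
                    bin_mm = 0.1, min_imaged_s = 6),
    oscillation = list(band_hz = c(6, 11)),
    profile = list(roi_radius_mm = 0.1, step_mm = 0.15, elev_tol_deg = 5,
                   smooth_frames = 5, n_starts = 16),
    simulate = list(duration_min = 2, frame_rate = 35, lfp_rate = 1000,
                    n_interictal = 10, n_seizures = 3),
    generator = generator_defaults()
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and out-of-range thresholds
#' (fractional thresholds in (0, 1], a low-high oscillation band, positive
#' rates).
#'
#' @param raw named list, path to a YAML/JSON file, or NULL for pure defaults.
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw)) {
    raw <- if (grepl("\\.ya?ml$", raw)) yaml::read_yaml(raw) else
      jsonlite::read_json(raw, simplifyVector = TRUE)
  }
  raw <- raw %||% list()
  def <- default_config()
  merge_checked <- function(d, r, path = "") {
    unknown <- setdiff(names(r), names(d))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (k in names(r)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(r[[k]]))
        merge_checked(d[[k]], r[[k]], paste0(path, k, "$")) else r[[k]]
    }
    d
  }
  cfg <- merge_checked(def, raw)
  frac <- function(x, nm) {
    if (!is.numeric(x) || x <= 0 || x > 1)
      stop(sprintf("config: %s must be in (0, 1]", nm), call. = FALSE)
  }
  frac(cfg$dff$baseline_percentile, "dff$baseline_percentile")
  frac(cfg$focus$threshold, "focus$threshold")
  frac(cfg$invasion$recruit_threshold, "invasion$recruit_threshold")
  frac(cfg$invasion$delay_threshold, "invasion$delay_threshold")
  b <- cfg$oscillation$band_hz
  if (length(b) != 2 || b[1] >= b[2] || b[1] <= 0)
    stop("config: oscillation$band_hz must be an increasing (low, high) pair",
         call. = FALSE)
  if (cfg$lfp$threshold_sd <= 0)
    stop("config: lfp$threshold_sd must be > 0", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full synthetic pipeline
#'
#' Simulates a session on the synthetic cortex (retinotopy mapping, interictal
#' events, seizures, LFP), then runs every analysis stage: LFP event detection
#' and classification, standing-wave fits of the interictal events, ROI-path
#' profiles with the contiguity x homotopy fit, delay maps with the speed
#' regression, and the oscillation phase-delay analysis. Returns a summary
#' list that is stable across runs with the same config and seed.
#'
#' @param config a `run_config` (see [validate_config()]); NULL for defaults.
#' @param stages character vector of stages to run; any of "events",
#'   "standing_wave", "profile", "invasion", "oscillation".
#' @return list with `summary` (named scalars), per-stage results and the
#'   config used.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("events", "standing_wave", "profile",
                                    "invasion", "oscillation")) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  g <- cfg$generator
  seed <- cfg$seed
  geom <- make_geometry()
  out <- list(config = cfg)
  summary <- list(seed = seed)

  ## --- LFP events ----------------------------------------------------------
  if ("events" %in% stages) {
    script <- make_event_script(duration_min = cfg$simulate$duration_min,
                                seed = seed, defaults = g)
    lfp <- render_lfp(script, lfp_rate = cfg$simulate$lfp_rate,
                      seed = seed + 1)
    ev <- detect_events(lfp, threshold_sd = cfg$lfp$threshold_sd,
                        refractory_s = cfg$lfp$refractory_s,
                        sustain_s = cfg$lfp$sustain_s)
    if (nrow(ev) >= 5) ev <- suppressWarnings(
      classify_events(ev, fallback_s = cfg$lfp$fallback_duration_s))
    out$events <- ev
    out$event_script <- script
    summary$n_events_detected <- nrow(ev)
    if (nrow(ev) && any(ev$class == "seizure", na.rm = TRUE))
      summary$seizure_median_duration_s <-
        stats::median(ev$duration_s[ev$class == "seizure"])
    if (nrow(ev) && any(ev$class == "interictal", na.rm = TRUE))
      summary$interictal_median_duration_s <-
        stats::median(ev$duration_s[ev$class == "interictal"])
  }

  ## --- interictal standing waves ------------------------------------------
  if ("standing_wave" %in% stages) {
    fits <- lapply(seq_len(cfg$simulate$n_interictal), function(i) {
      sc <- single_event_script("interictal", defaults = g)
      mov <- render_event_movie(geom, sc,
                                frame_rate = cfg$simulate$frame_rate,
                                seed = seed + 100 + i)
      fit_standing_wave(mov, window = c(0, sc$duration_s[1]))
    })
    out$standing_wave <- fits
    avg <- average_event_map(fits)
    out$mean_map <- avg
    summary$standing_wave_ve_pct <- 100 * mean(avg$ve)
    summary$max_rms_residual_pct <- 100 *
      max(vapply(fits, function(f) max(f$rms_residual_series), numeric(1)))
  }

  ## --- profiles ------------------------------------------------------------
  if ("profile" %in% stages) {
    session <- render_retinotopy_session(geom, seed = seed + 2)
    rmap <- map_retinotopy(session)
    path <- build_roi_path(rmap$azimuth, geom$area, geom$elevation,
                           geom$focus_rc, geom$pixel_pitch,
                           roi_radius = cfg$profile$roi_radius_mm,
                           step = cfg$profile$step_mm,
                           elev_tol = cfg$profile$elev_tol_deg)
    sc <- single_event_script("interictal", defaults = g)
    mov <- render_event_movie(geom, sc,
                              frame_rate = cfg$simulate$frame_rate,
                              seed = seed + 3)
    prof <- extract_profile(mov, path, c(0, sc$duration_s[1]),
                            smooth_frames = cfg$profile$smooth_frames)
    pfit <- fit_profile_model(prof, n_starts = cfg$profile$n_starts)
    out$roi_path <- path
    out$profile_fit <- pfit
    summary$profile_sigma_deg <- unname(pfit$par["sigma"])
    summary$profile_lambda_mm <- unname(pfit$par["lambda"])
  }

  ## --- seizure invasion ----------------------------------------------------
  if ("invasion" %in% stages) {
    dur <- 8
    maps <- lapply(seq_len(cfg$simulate$n_seizures), function(i) {
      sc <- single_event_script("seizure", duration_s = dur, defaults = g)
      mov <- render_event_movie(geom, sc,
                                frame_rate = cfg$simulate$frame_rate,
                                seed = seed + 200 + i)
      rec <- recruited_mask(mov, focus_peak = g$seizure_peak,
                            threshold = cfg$invasion$recruit_threshold)
      compute_delay_map(mov, onset_s = 0, recruited = rec,
                        threshold = cfg$invasion$delay_threshold)
    })
    sfit <- speed_regression(maps, geom, bin_mm = cfg$invasion$bin_mm)
    out$delay_maps <- maps
    out$speed_fit <- sfit
    summary$speed_mm_s <- sfit$speed_mm_s
    summary$r_delay_distance <- sfit$r_delay_distance
    summary$r_resid_retinotopy <- sfit$r_resid_retinotopy
  }

  ## --- ictal oscillations --------------------------------------------------
  if ("oscillation" %in% stages) {
    sc <- single_event_script("seizure", duration_s = 8, defaults = g)
    mov <- render_event_movie(geom, sc,
                              frame_rate = cfg$simulate$frame_rate,
                              seed = seed + 300)
    am <- analytic_movie(mov, band = cfg$oscillation$band_hz)
    pdm <- phase_delay_map(am, geom$focus_rc, epoch = c(4, 7.5))
    out$phase_delay <- pdm
    summary$osc_focus_freq_hz <- pdm$focus_freq_hz
    summary$osc_median_lag_ms <- 1000 *
      stats::median(pdm$lag_s, na.rm = TRUE)
  }

  out$summary <- summary
  out
}
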