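## LFP epileptiform event detection, classification and triggered summaries.

#' LFP trace container
#'
#' @param samples numeric vector in mV.
#' @param rate sample rate in Hz (> 0).
#' @return object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, rate) {
  stopifnot_scalar(rate, "rate", positive = TRUE)
  if (!all(is.finite(samples)))
    stop("LFP samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %.1f s at %g Hz (%d samples)\n",
              length(x$samples) / x$rate, x$rate, length(x$samples)))
  invisible(x)
}

## resample to `target` Hz by chained FIR decimation (factors <= 10)
resample_lfp <- function(trace, target = 100) {
  x <- trace$samples
  rate <- trace$rate
  if (abs(rate - target) < 1e-9) return(list(samples = x, rate = rate))
  q <- rate / target
  if (abs(q - round(q)) > 1e-6)
    stop("sample rate must be an integer multiple of the target rate",
         call. = FALSE)
  q <- round(q)
  while (q > 1) {
    step <- if (q %% 10 == 0) 10 else if (q %% 5 == 0) 5 else
      if (q %% 2 == 0) 2 else q
    x <- signal::decimate(x, step, ftype = "fir")
    q <- q / step
  }
  list(samples = x, rate = target)
}

## low-frequency envelope: magnitude of the analytic signal of the < 5 Hz
## low-passed trace
lfp_envelope <- function(x, rate, cutoff = 5) {
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  lo <- signal::filtfilt(bf, x)
  Mod(analytic_signal(lo))
}

#' Detect epileptiform events on an LFP trace
#'
#' The trace is resampled to 100 Hz. Candidate onsets are local maxima of the
#' absolute first derivative exceeding three standard deviations of the
#' derivative over the full trace; candidates within the refractory window of
#' the previous onset, or occurring before the previous event has ended, are
#' discarded. Each event ends when the low-frequency (< 5 Hz) envelope stays
#' below baseline + 1 SD for at least 200 ms; the offset is the start of that
#' sustained return.
#'
#' @param lfp an [lfp_trace()] of at least 10 s.
#' @param threshold_sd derivative threshold in SDs, default 3.
#' @param refractory_s merge window for multi-peak onsets, default 0.3 s.
#' @param sustain_s sustained envelope-return requirement, default 0.2 s.
#' @return an `event_table`: data.frame with onset_s, offset_s, duration_s,
#'   amplitude_mv (peak negative deflection), interval_s (time to next onset)
#'   and class = NA (see [classify_events()]). Zero rows if nothing crosses
#'   threshold.
#' @export
detect_events <- function(lfp, threshold_sd = 3, refractory_s = 0.3,
                          sustain_s = 0.2) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (length(lfp$samples) / lfp$rate < 10)
    stop("trace must be at least 10 s long", call. = FALSE)
  rs <- resample_lfp(lfp, 100)
  x <- rs$samples; rate <- rs$rate
  dv <- c(0, diff(x)) * rate
  sd_dv <- stats::sd(dv)
  empty <- structure(
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               duration_s = numeric(0), amplitude_mv = numeric(0),
               interval_s = numeric(0), class = character(0)),
    class = c("event_table", "data.frame"))
  if (sd_dv == 0) return(empty)
  a <- abs(dv)
  thr <- threshold_sd * sd_dv
  n <- length(a)
  is_peak <- a > thr &
    a >= c(-Inf, a[-n]) & a >= c(a[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(empty)

  env <- lfp_envelope(x, rate)
  base <- stats::median(env)
  sd_env <- 1.4826 * stats::mad(env)
  below <- env < base + sd_env
  sustain_n <- max(1L, round(sustain_s * rate))
  ## forward lengths of below-threshold runs starting at each index
  runlen <- integer(n); acc <- 0L
  for (i in n:1) {
    acc <- if (below[i]) acc + 1L else 0L
    runlen[i] <- acc
  }

  onsets <- offsets <- numeric(0)
  last_end_idx <- 0L
  last_onset <- -Inf
  for (ci in cand) {
    t_on <- (ci - 1) / rate
    if (ci <= last_end_idx) next
    if (t_on - last_onset < refractory_s) next
    after <- which(runlen[ci:n] >= sustain_n)
    end_idx <- if (length(after)) ci + after[1] - 1L else n
    onsets <- c(onsets, t_on)
    offsets <- c(offsets, (end_idx - 1) / rate)
    last_end_idx <- end_idx
    last_onset <- t_on
  }
  if (!length(onsets)) return(empty)
  base_v <- stats::median(x)
  amp <- vapply(seq_along(onsets), function(i) {
    i0 <- round(onsets[i] * rate) + 1
    i1 <- min(n, round(min(offsets[i], onsets[i] + 1) * rate) + 1)
    base_v - min(x[i0:i1])
  }, numeric(1))
  structure(
    data.frame(onset_s = onsets, offset_s = offsets,
               duration_s = offsets - onsets, amplitude_mv = amp,
               interval_s = c(diff(onsets), NA_real_),
               class = NA_character_),
    class = c("event_table", "data.frame"))
}

#' Classify detected events as interictal or seizure by duration
#'
#' Splits the (bimodal) log-duration distribution with an exhaustive two-class
#' threshold minimising within-class variance; the shorter class is labelled
#' interictal, the longer seizure. If the two classes are not well separated
#' (ratio of class medians < 4) a warning is issued and the fixed fallback
#' threshold of 2 s is applied.
#'
#' @param events an `event_table` with at least 5 events.
#' @param fallback_s fallback duration threshold, default 2 s.
#' @return the `event_table` with the `class` column filled in.
#' @export
classify_events <- function(events, fallback_s = 2) {
  stopifnot(inherits(events, "event_table"))
  if (nrow(events) < 5)
    stop("need at least 5 events to classify", call. = FALSE)
  ld <- sort(log(events$duration_s))
  n <- length(ld)
  ## exhaustive two-class split minimising the within-class sum of squares
  cs <- cumsum(ld); cs2 <- cumsum(ld^2)
  ss_left <- cs2[1:(n - 1)] - cs[1:(n - 1)]^2 / (1:(n - 1))
  nr <- n - (1:(n - 1))
  ss_right <- (cs2[n] - cs2[1:(n - 1)]) - (cs[n] - cs[1:(n - 1)])^2 / nr
  best_k <- which.min(ss_left + ss_right)
  thr <- exp((ld[best_k] + ld[best_k + 1]) / 2)
  lo <- events$duration_s <= thr
  sep <- stats::median(events$duration_s[!lo]) /
    stats::median(events$duration_s[lo])
  if (!any(lo) || all(lo) || !is.finite(sep) || sep < 4) {
    warning("duration distribution not clearly bimodal; applying fallback threshold",
            call. = FALSE)
    thr <- fallback_s
  }
  events$class <- ifelse(events$duration_s <= thr, "interictal", "seizure")
  attr(events, "duration_threshold_s") <- thr
  events
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events", nrow(x)))
  if (nrow(x) && any(!is.na(x$class))) {
    tb <- table(x$class)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Event-triggered average of an arbitrary trace
#'
#' Averages trace segments time-locked to a set of onsets. Onsets whose window
#' does not fit inside the trace are excluded and counted.
#'
#' @param x numeric trace.
#' @param rate sample rate of `x` in Hz.
#' @param onsets onset times in seconds.
#' @param window numeric (pre, post) in seconds, e.g. c(-1, 3).
#' @return list with `time` (s, relative to onset), `mean`, `sem`, `n_used`,
#'   `n_clipped`.
#' @export
triggered_average <- function(x, rate, onsets, window = c(-1, 3)) {
  i_pre <- round(window[1] * rate)
  i_post <- round(window[2] * rate)
  rel <- i_pre:i_post
  segs <- lapply(onsets, function(t0) {
    i0 <- round(t0 * rate) + 1
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(x)) return(NULL)
    x[idx]
  })
  keep <- !vapply(segs, is.null, logical(1))
  if (!any(keep))
    stop("no onset has a full window inside the trace", call. = FALSE)
  M <- do.call(rbind, segs[keep])
  mu <- colMeans(M)
  sem <- if (nrow(M) > 1) apply(M, 2, stats::sd) / sqrt(nrow(M)) else
    rep(0, ncol(M))
  list(time = rel / rate, mean = mu, sem = sem,
       n_used = nrow(M), n_clipped = sum(!keep))
}

#' Band-limited power change during an event
#'
#' Ratio of band power during the event to band power in a preceding baseline
#' segment, using a Welch-style averaged-periodogram estimate (segments of
#' 2 s with 50% overlap, Hann window).
#'
#' @param lfp an [lfp_trace()].
#' @param event numeric (onset_s, offset_s).
#' @param band numeric (low, high) in Hz, default c(6, 30).
#' @param baseline_s baseline length in seconds ending at the event onset.
#' @return the power ratio (event / baseline).
#' @export
band_power_change <- function(lfp, event, band = c(6, 30), baseline_s = 5) {
  stopifnot(inherits(lfp, "lfp_trace"))
  if (baseline_s < 2 / band[1])
    stop("baseline shorter than 2 / low-cut seconds", call. = FALSE)
  r <- lfp$rate
  seg <- function(t0, t1) {
    i0 <- max(1, round(t0 * r) + 1); i1 <- min(length(lfp$samples),
                                               round(t1 * r))
    lfp$samples[i0:i1]
  }
  bp <- function(x) {
    nwin <- min(length(x), round(2 * r))
    step <- max(1, floor(nwin / 2))
    starts <- seq(1, length(x) - nwin + 1, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
    ps <- 0
    for (s in starts) {
      z <- (x[s:(s + nwin - 1)] - mean(x[s:(s + nwin - 1)])) * w
      ps <- ps + Mod(stats::fft(z))^2 / sum(w^2)
    }
    ps <- ps / length(starts)
    f <- (seq_len(nwin) - 1) * r / nwin
    sum(ps[f >= band[1] & f <= band[2]])
  }
  bp(seg(event[1], event[2])) / bp(seg(event[1] - baseline_s, event[1]))
}

#' Write / read an event table as CSV
#'
#' @param events an `event_table`.
#' @param path CSV path.
#' @return `read_event_table` returns an `event_table`.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("event_table", "data.frame"))
}
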