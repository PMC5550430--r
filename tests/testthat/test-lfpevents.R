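test_that("a flat trace yields an empty event table", {
  lfp <- lfp_trace(rep(0, 20 * 1000), 1000)
  ev <- detect_events(lfp)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 0)
})

test_that("one planted large step is detected once, at the right time", {
  set.seed(14)
  rate <- 1000
  x <- rnorm(30 * rate, sd = 0.05)
  t0 <- 12.0
  ## sustained 20-SD step; the envelope never returns to baseline afterwards
  x[(seq_along(x) - 1) / rate >= t0] <-
    x[(seq_along(x) - 1) / rate >= t0] - 1.0
  ev <- detect_events(lfp_trace(x, rate))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_s[1] - t0), 0.02)
})

test_that("noise-only false positives match a direct threshold-scan oracle", {
  set.seed(15)
  rate <- 1000
  x <- rnorm(120 * rate, sd = 0.05)
  lfp <- lfp_trace(x, rate)
  ev <- detect_events(lfp)
  ## oracle: same resampling, same derivative, direct scan for local maxima
  ## above 3 SD followed by the same refractory rule
  rs <- ictalwave:::resample_lfp(lfp, 100)
  dv <- c(0, diff(rs$samples)) * 100
  a <- abs(dv); thr <- 3 * sd(dv); n <- length(a)
  peaks <- which(a > thr & a >= c(-Inf, a[-n]) & a >= c(a[-1], -Inf))
  expect_lte(nrow(ev), length(peaks))
  ## every reported onset must be one of the oracle's threshold crossings
  expect_true(all((round(ev$onset_s * 100) + 1) %in% peaks))
})

test_that("well-separated durations split into interictal and seizure", {
  ev <- structure(data.frame(onset_s = seq(0, 250, by = 50),
                             offset_s = seq(0, 250, by = 50) +
                               c(0.4, 0.5, 0.6, 8, 9, 10),
                             duration_s = c(0.4, 0.5, 0.6, 8, 9, 10),
                             amplitude_mv = 1, interval_s = NA,
                             class = NA_character_),
                  class = c("event_table", "data.frame"))
  out <- classify_events(ev)
  expect_equal(out$class, rep(c("interictal", "seizure"), each = 3))
})

test_that("unimodal durations fall back to the fixed threshold", {
  ev <- structure(data.frame(onset_s = 1:6 * 10, offset_s = 1:6 * 10 + 0.5,
                             duration_s = rep(0.5, 6), amplitude_mv = 1,
                             interval_s = NA, class = NA_character_),
                  class = c("event_table", "data.frame"))
  expect_warning(out <- classify_events(ev), "bimodal")
  expect_true(all(out$class == "interictal"))
})

test_that("classification is invariant to event ordering", {
  dur <- c(0.4, 9, 0.6, 8, 0.5, 10, 0.45)
  mk <- function(d) structure(
    data.frame(onset_s = seq_along(d) * 20, offset_s = seq_along(d) * 20 + d,
               duration_s = d, amplitude_mv = 1, interval_s = NA,
               class = NA_character_),
    class = c("event_table", "data.frame"))
  a <- classify_events(mk(dur))
  b <- classify_events(mk(rev(dur)))
  expect_equal(a$class, rev(b$class))
})

test_that("detection hits planted onsets with high precision and recall", {
  sc <- make_event_script(duration_min = 10, seed = 16)
  lfp <- render_lfp(sc, seed = 17)
  ev <- detect_events(lfp)
  gt <- attr(lfp, "ground_truth")
  prec <- mean(vapply(ev$onset_s,
                      function(o) min(abs(gt$onset_s - o)) < 0.25,
                      logical(1)))
  rec <- mean(vapply(gt$onset_s,
                     function(o) any(abs(ev$onset_s - o) < 0.25),
                     logical(1)))
  expect_gte(prec, 0.95)
  expect_gte(rec, 0.95)
})

test_that("class medians recover the planted duration medians", {
  sc <- make_event_script(duration_min = 20, seed = 18)
  lfp <- render_lfp(sc, seed = 19)
  ev <- suppressWarnings(classify_events(detect_events(lfp)))
  gt <- attr(lfp, "ground_truth")
  for (cl in c("interictal", "seizure")) {
    planted <- median(gt$offset_s[gt$class == cl] - gt$onset_s[gt$class == cl])
    detected <- median(ev$duration_s[ev$class == cl])
    expect_lt(abs(detected - planted) / planted, 0.15)
  }
})

test_that("triggered averages reproduce an identical waveform with zero sem", {
  rate <- 100
  w <- sin(seq(0, 2 * pi, length.out = 101))
  x <- rep(0, 60 * rate)
  onsets <- c(5, 15, 25, 35)
  for (t0 in onsets) x[t0 * rate + 1 + (0:100)] <- w
  ta <- triggered_average(x, rate, onsets, window = c(0, 1))
  expect_equal(ta$mean, w, tolerance = 1e-12)
  expect_equal(max(ta$sem), 0)
  expect_equal(ta$n_used, 4)
  ## single onset: the average is the raw segment
  ta1 <- triggered_average(x, rate, onsets[1], window = c(0, 1))
  expect_equal(ta1$mean, w)
  ## clipped onsets are excluded and counted
  ta2 <- triggered_average(x, rate, c(onsets, 59.9), window = c(0, 1))
  expect_equal(ta2$n_clipped, 1)
  expect_error(triggered_average(x, rate, 59.99, window = c(0, 1)), "window")
})

test_that("triggered-average sem shrinks as noise / sqrt(n)", {
  set.seed(20)
  rate <- 100
  n_ev <- 100
  w <- cos(seq(0, 2 * pi, length.out = 51))
  x <- rnorm(800 * rate, sd = 0.5)
  onsets <- seq(4, 796, length.out = n_ev)
  for (t0 in onsets) x[round(t0 * rate) + 1 + (0:50)] <-
      x[round(t0 * rate) + 1 + (0:50)] + w
  ta <- triggered_average(x, rate, onsets, window = c(0, 0.5))
  expect_equal(mean(ta$sem), 0.5 / sqrt(n_ev), tolerance = 0.15)
  expect_equal(ta$mean, w, tolerance = 0.25)
})

test_that("band power ratios respond to an added in-band oscillation", {
  set.seed(22)
  rate <- 1000
  x <- rnorm(60 * rate, sd = 0.1)
  tt <- (seq_along(x) - 1) / rate
  ev <- c(30, 40)
  in_ev <- tt >= ev[1] & tt < ev[2]
  x[in_ev] <- x[in_ev] + 0.3 * sin(2 * pi * 10 * tt[in_ev])
  lfp <- lfp_trace(x, rate)
  expect_gt(band_power_change(lfp, ev, band = c(6, 30), baseline_s = 5), 2)
  ## identical statistics pre/during: ratio near 1
  x2 <- rnorm(60 * rate, sd = 0.1)
  expect_equal(band_power_change(lfp_trace(x2, rate), ev, c(6, 30), 5), 1,
               tolerance = 0.25)
  ## band without signal content: ratio near 1
  expect_equal(band_power_change(lfp, ev, band = c(100, 200), baseline_s = 5),
               1, tolerance = 0.25)
  expect_error(band_power_change(lfp, ev, band = c(6, 30), baseline_s = 0.1),
               "baseline")
})

test_that("event tables survive a CSV round trip", {
  sc <- make_event_script(duration_min = 5, seed = 23)
  lfp <- render_lfp(sc, seed = 24)
  ev <- detect_events(lfp)
  p <- file.path(tempdir(), "events.csv")
  write_event_table(ev, p)
  back <- read_event_table(p)
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$duration_s, ev$duration_s)
})
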