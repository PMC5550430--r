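## helper: analytic movie straight from a time x pixels matrix
am_from <- function(X, nr, nc, frame_rate = 35)
  analytic_movie(matrix_movie(X, nr, nc, frame_rate = frame_rate),
                 band = c(6, 11))

test_that("a pure in-band tone has unit amplitude and its own frequency", {
  fr <- 35; tt <- (0:349) / fr
  X <- matrix(cos(2 * pi * 8 * tt), ncol = 1)
  am <- am_from(X, 1, 1, fr)
  mid <- 100:250
  expect_equal(mean(am$amplitude[mid, 1, 1]), 1, tolerance = 0.02)
  inst_f <- diff(ictalwave:::unwrap_phase(am$phase[mid, 1, 1])) * fr / (2 * pi)
  expect_equal(mean(inst_f), 8, tolerance = 0.05)
})

test_that("a 13 ms lag at 8 Hz appears as 0.653 rad of phase", {
  fr <- 70; tt <- (0:699) / fr
  lag <- 0.013
  X <- cbind(cos(2 * pi * 8 * tt), cos(2 * pi * 8 * (tt - lag)))
  am <- am_from(X, 1, 2, fr)
  mid <- 200:500
  dphi <- ictalwave:::wrap_pi(am$phase[mid, 1, 1] - am$phase[mid, 1, 2])
  expect_equal(mean(dphi), 2 * pi * 8 * lag, tolerance = 0.01)
  expect_equal(2 * pi * 8 * lag, 0.6535, tolerance = 1e-3)
})

test_that("zero traces get zero amplitude and undefined phase", {
  X <- cbind(rep(0, 200), cos(2 * pi * 8 * (0:199) / 35))
  am <- am_from(X, 1, 2)
  expect_equal(max(am$amplitude[, 1, 1]), 0)
  expect_true(all(is.na(am$phase[, 1, 1])))
})

test_that("an undersampled or too-short movie is rejected", {
  X <- matrix(rnorm(300), ncol = 2)
  expect_error(analytic_movie(matrix_movie(X, 1, 2, frame_rate = 20)),
               "frame rate")
  expect_error(analytic_movie(matrix_movie(X[1:20, ], 1, 2,
                                           frame_rate = 35)),
               "periods")
})

test_that("uniform in-phase oscillations give zero lag everywhere", {
  fr <- 35; tt <- (0:299) / fr
  X <- matrix(cos(2 * pi * 8 * tt), 300, 24)
  am <- am_from(X, 4, 6, fr)
  pdm <- phase_delay_map(am, c(2, 3), epoch = c(3, 7))
  expect_lt(max(abs(pdm$lag_s), na.rm = TRUE), 1e-6)
})

test_that("planted lag fields are recovered to millisecond accuracy", {
  fr <- 35; tt <- (0:349) / fr
  set.seed(31)
  lags <- matrix(runif(36, 0, 0.02), 6, 6); lags[2, 3] <- 0
  X <- vapply(as.vector(lags), function(l) cos(2 * pi * 8 * (tt - l)),
              numeric(length(tt)))
  am <- am_from(X, 6, 6, fr)
  pdm <- phase_delay_map(am, c(2, 3), epoch = c(2, 8))
  expect_lt(sqrt(mean((pdm$lag_s - lags)^2, na.rm = TRUE)), 0.002)
})

test_that("a half-period lag maps to +T/2 by the wrapping convention", {
  expect_equal(ictalwave:::wrap_pi(pi), pi)
  expect_equal(ictalwave:::wrap_pi(-pi), pi)
  fr <- 40; tt <- (0:399) / fr
  X <- cbind(cos(2 * pi * 8 * tt), cos(2 * pi * 8 * tt - pi))
  am <- am_from(X, 1, 2, fr)
  pdm <- phase_delay_map(am, c(1, 1), epoch = c(2, 8))
  T8 <- 1 / pdm$focus_freq_hz
  expect_equal(pdm$lag_s[1, 2], T8 / 2, tolerance = 0.002)
})

test_that("phase-delay maps ignore global amplitude scaling", {
  mov <- seizure_movie(seed = 81, noise_sd = 0)
  am1 <- analytic_movie(mov)
  scaled <- mov; scaled$frames <- scaled$frames * 7.3
  am2 <- analytic_movie(scaled)
  p1 <- phase_delay_map(am1, default_geom$focus_rc, epoch = c(6.8, 8.2))
  p2 <- phase_delay_map(am2, default_geom$focus_rc, epoch = c(6.8, 8.2))
  expect_equal(p1$lag_s, p2$lag_s, tolerance = 1e-9)
})

test_that("oscillation lags track the planted slow delay field", {
  mov <- seizure_movie(seed = 82, noise_sd = 0)
  am <- analytic_movie(mov)
  pdm <- phase_delay_map(am, default_geom$focus_rc, epoch = c(6.8, 8.2))
  planted <- plant_delay_field(default_geom)
  ok <- is.finite(pdm$lag_s) & is.finite(planted)
  expect_gt(cor(pdm$lag_s[ok], planted[ok], method = "spearman"), 0.9)
})

test_that("cycle averages preserve waveform shape", {
  fr <- 200; tt <- (0:(8 * fr - 1)) / fr
  ref <- ictalwave:::wrap_pi(2 * pi * 8 * tt)
  ## pure sinusoid: one clean cycle, near-zero SD
  ca <- cycle_average(sin(2 * pi * 8 * tt), ref)
  expect_lt(max(ca$sd[5:95]), 0.02)
  expect_equal(max(ca$mean), 1, tolerance = 0.02)
  ## sawtooth stays asymmetric (not sinusoidalised): one jump much larger
  ## than the typical slope survives the averaging
  saw <- ((8 * tt) %% 1)
  cs <- cycle_average(saw, ref)
  expect_gt(max(abs(diff(cs$mean))), 6 * median(abs(diff(cs$mean))))
  ## noise averages down across many cycles
  set.seed(32)
  noisy <- sin(2 * pi * 8 * tt) + rnorm(length(tt), sd = 0.5)
  cn <- cycle_average(noisy, ref)
  expect_equal(cn$mean, ca$mean, tolerance = 0.35)
  ## linear resampling averages neighbouring samples, so the per-point SD
  ## sits a little below the raw noise SD
  expect_gt(median(cn$sd), 0.3)
  expect_lt(median(cn$sd), 0.55)
  expect_error(cycle_average(sin(2 * pi * 8 * tt[1:30]), ref[1:30]),
               "cycles")
})

test_that("spatial phase variance spans its closed-form cases", {
  fr <- 35; tt <- (0:199) / fr
  mk <- function(phases) {
    X <- vapply(phases, function(p) cos(2 * pi * 8 * tt - p),
                numeric(length(tt)))
    am_from(X, 4, length(phases) / 4, fr)
  }
  expect_lt(spatial_phase_variance(mk(rep(0.3, 16)), 100), 0.01)
  expect_gt(spatial_phase_variance(mk(seq(0, 2 * pi, length.out = 17)[-17]),
                                   100), 0.9)
  expect_equal(spatial_phase_variance(mk(rep(c(0, pi), each = 8)), 100), 1,
               tolerance = 0.01)
})

test_that("pinwheel detection finds singularities and conserves charge", {
  nr <- 32; nc <- 32
  mkam <- function(ph) {
    structure(list(amplitude = array(1, c(1, nr, nc)),
                   phase = array(ph, c(1, nr, nc)),
                   band = c(6, 11), frame_times = 0,
                   mask = matrix(TRUE, nr, nc), pixel_pitch = 0.05),
              class = "analytic_movie")
  }
  yy <- row(matrix(0, nr, nc)); xx <- col(matrix(0, nr, nc))
  ## single positive spiral at (16.5, 16.5)
  ph1 <- atan2(yy - 16.5, xx - 16.5)
  pw <- detect_pinwheels(mkam(ph1), 1)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$winding, 1)
  expect_equal(c(pw$row, pw$col), c(16, 16))
  ## plane wave: no singularities
  ph2 <- ictalwave:::wrap_pi(0.4 * xx)
  expect_equal(nrow(detect_pinwheels(mkam(ph2), 1)), 0)
  ## opposite spiral pair (cores between grid points): charges +1 and -1
  ph3 <- ictalwave:::wrap_pi(atan2(yy - 16.5, xx - 8.5) -
                               atan2(yy - 16.5, xx - 24.5))
  pw3 <- detect_pinwheels(mkam(ph3), 1)
  expect_equal(sort(pw3$winding), c(-1, 1))
  expect_equal(sum(pw3$winding), 0)
  ## topological consistency: boundary winding equals the summed charges
  for (ph in list(ph1, ph2, ph3))
    expect_equal(boundary_winding(ph),
                 sum(detect_pinwheels(mkam(ph), 1)$winding))
})

test_that("spiral cores sit at low amplitude when planted so", {
  nr <- 24; nc <- 24
  yy <- row(matrix(0, nr, nc)); xx <- col(matrix(0, nr, nc))
  r2 <- (yy - 12.5)^2 + (xx - 12.5)^2
  am <- structure(list(amplitude = array(sqrt(r2) / max(sqrt(r2)),
                                         c(1, nr, nc)),
                       phase = array(atan2(yy - 12.5, xx - 12.5),
                                     c(1, nr, nc)),
                       band = c(6, 11), frame_times = 0,
                       mask = matrix(TRUE, nr, nc), pixel_pitch = 0.05),
                  class = "analytic_movie")
  pw <- detect_pinwheels(am, 1)
  expect_true(all(pw$is_amp_minimum))
})
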