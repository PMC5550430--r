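test_that("second-harmonic amplitude recovers a pure tone exactly", {
  fr <- 50; tt <- (0:249) / fr
  A <- 0.7
  X <- cbind(A * cos(2 * pi * 4 * tt),       # exactly the second harmonic
             rep(0.3, length(tt)),           # constant -> 0
             A * cos(2 * pi * 4 * tt + 1))   # amplitude is phase-invariant
  mov <- matrix_movie(X, 1, 3, frame_rate = fr)
  amp <- second_harmonic_power(mov, reversal_rate = 2)
  expect_equal(amp[1, 1], A, tolerance = 1e-9)
  expect_equal(amp[1, 2], 0, tolerance = 1e-9)
  expect_equal(amp[1, 3], A, tolerance = 1e-9)
})

test_that("second-harmonic amplitude is linear in trace amplitude", {
  fr <- 50; tt <- (0:199) / fr
  set.seed(2)
  base <- cos(2 * pi * 4 * tt) + 0.3 * rnorm(length(tt))
  mov <- matrix_movie(cbind(base, 2 * base), 1, 2, frame_rate = fr)
  amp <- second_harmonic_power(mov, 2)
  expect_equal(amp[1, 2], 2 * amp[1, 1], tolerance = 1e-9)
})

test_that("white noise produces a near-zero second-harmonic amplitude", {
  fr <- 50; n <- 250
  set.seed(101)
  sd_n <- 0.1; A <- 10 * sd_n
  X <- matrix(rnorm(n * 40, sd = sd_n), n, 40)
  amp <- second_harmonic_power(matrix_movie(X, 4, 10, frame_rate = fr), 2)
  ## Monte-Carlo bound: all noise amplitudes stay below A / 10
  expect_true(all(amp < A / 10))
})

test_that("aliasing and short epochs are rejected", {
  X <- matrix(rnorm(100), 50, 2)
  expect_error(second_harmonic_power(matrix_movie(X, 1, 2, frame_rate = 6), 2),
               "aliasing|frame rate")
  expect_error(second_harmonic_power(matrix_movie(X[1:5, ], 1, 2,
                                                  frame_rate = 50), 2),
               "cycles")
})

test_that("position tuning recovers centre and width from clean data", {
  positions <- c(17.5, 52.5, 87.5, 122.5)
  true_c <- 60; true_s <- 25
  amps <- matrix(exp(-(positions - true_c)^2 / (2 * true_s^2)), 1)
  amps <- rbind(amps, 0.5 * amps)           # gain differences are fine
  fit <- fit_position_tuning(amps, positions)
  expect_equal(fit$preferred, rep(true_c, 2), tolerance = 0.5)
  expect_equal(fit$sigma_t, true_s, tolerance = 1.01)
})

test_that("flat or zero pixels are flagged missing", {
  positions <- c(10, 50, 90, 130)
  amps <- rbind(rep(0.4, 4), rep(0, 4),
                exp(-(positions - 70)^2 / (2 * 25^2)))
  fit <- fit_position_tuning(amps, positions)
  expect_true(is.na(fit$preferred[1]))
  expect_true(is.na(fit$preferred[2]))
  expect_false(is.na(fit$preferred[3]))
})

test_that("the shared width equals the brute-force grid minimiser", {
  positions <- c(20, 60, 100, 140)
  set.seed(3)
  amps <- matrix(exp(-(positions - 80)^2 / (2 * 30^2)) + 0.02 * rnorm(4), 1)
  amps[amps < 0] <- 0
  fit <- fit_position_tuning(amps, positions, sigma_grid = c(10, 30))
  ## oracle: evaluate the full (centre, sigma) grid exhaustively
  centers <- seq(0, 160, by = 1)
  best <- Inf; best_sg <- NA
  for (sg in c(10, 30)) {
    sse_min <- Inf
    for (cc in centers) {
      m <- exp(-(positions - cc)^2 / (2 * sg^2))
      g <- max(0, sum(amps * m) / sum(m^2))
      sse <- sum((amps - g * m)^2)
      sse_min <- min(sse_min, sse)
    }
    if (sse_min < best) { best <- sse_min; best_sg <- sg }
  }
  expect_equal(fit$sigma_t, best_sg)
})

test_that("noiseless sessions recover the azimuth map to sub-degree RMS", {
  ses <- render_retinotopy_session(default_geom, seed = 1)
  rmap <- map_retinotopy(ses)
  err <- rmap$azimuth - default_geom$azimuth
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)
})

test_that("the ROI path marches straight along the azimuth gradient", {
  path <- build_roi_path(default_geom$azimuth, default_geom$area,
                         default_geom$elevation, default_geom$focus_rc,
                         default_geom$pixel_pitch)
  ## linear gradient along +x: straight horizontal line
  expect_true(all(path$row == path$row[1]))
  expect_true(all(diff(path$col) > 0))
  ## starts at the focus
  expect_equal(unname(unlist(path[1, c("row", "col")])),
               unname(default_geom$focus_rc))
  expect_equal(path$distance_mm[1], 0)
  ## azimuth monotone decreasing in V1 then increasing in LM (mirror)
  az_v1 <- path$azimuth_deg[path$area == 1L]
  az_lm <- path$azimuth_deg[path$area == 2L]
  expect_true(all(diff(az_v1) < 0))
  expect_true(all(diff(az_lm) > 0))
  ## consecutive centres within 2 x ROI radius
  stepd <- sqrt(diff(path$row)^2 + diff(path$col)^2) *
    default_geom$pixel_pitch
  expect_true(all(stepd <= 2 * attr(path, "roi_radius_mm") + 1e-9))
  ## elevation iso-band: all ROIs within tolerance of the focus elevation
  fel <- default_geom$elevation[default_geom$focus_rc[1],
                                default_geom$focus_rc[2]]
  els <- default_geom$elevation[cbind(path$row, path$col)]
  expect_true(all(abs(els - fel) <= 5))
})

test_that("a path that cannot reach LM reports the failure point", {
  area_v1_only <- default_geom$area
  area_v1_only[area_v1_only == 2L] <- 0L
  expect_error(build_roi_path(default_geom$azimuth, area_v1_only,
                              default_geom$elevation, default_geom$focus_rc,
                              default_geom$pixel_pitch),
               "LM")
})
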