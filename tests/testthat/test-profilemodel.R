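test_that("the homotopy term satisfies its closed-form identities", {
  expect_equal(homotopy_term(93, sigma = 25, R_focus = 93), 1.0)
  ## half maximum at sigma * sqrt(2 ln 2)
  expect_equal(homotopy_term(93 + 25 * sqrt(2 * log(2)), 25, 93), 0.5,
               tolerance = 1e-12)
  ## two sigmas out: exp(-2)
  expect_equal(homotopy_term(93 + 50, 25, 93), exp(-2), tolerance = 1e-12)
  expect_error(homotopy_term(0, sigma = 0, R_focus = 0), "sigma")
})

test_that("the contiguity term is a flat-top with lambda as HWHM", {
  a <- 1.3; b <- 0.2; lam <- 0.7; x0 <- 1.1
  expect_equal(contiguity_term(x0, lam, a, b, x0), a)
  expect_equal(contiguity_term(x0 + lam, lam, a, b, x0), (a + b) / 2,
               tolerance = 1e-12)
  expect_equal(contiguity_term(x0 - lam, lam, a, b, x0), (a + b) / 2,
               tolerance = 1e-12)
  ## a = 1, b = 0 at two HWHM: 2^-16
  expect_equal(contiguity_term(2, 1, 1, 0, 0), 2^-16, tolerance = 1e-12)
  expect_error(contiguity_term(0, 0, 1, 0, 0), "lambda")
})

test_that("huge sigma reduces the model to the contiguity term alone", {
  x <- seq(0, 3, by = 0.2); R <- seq(140, 0, length.out = length(x))
  par <- list(sigma = 1e9, lambda = 0.6, a = 1.25, b = 0.05,
              R_focus = 93, x_focus = 0.7)
  pred <- ictalwave:::profile_model_predict(par, x, R)
  expect_equal(pred, contiguity_term(x, 0.6, 1.25, 0.05, 0.7),
               tolerance = 1e-9)
})

test_that("noiseless profiles recover planted parameters within 1%", {
  x <- seq(0, 3, by = 0.15)
  R <- ifelse(x < 2.2, 140 - x / 2.2 * 140, (x - 2.2) / 0.95 * 140)
  truth <- list(sigma = 25, lambda = 0.6, a = 1.25, b = 0.05,
                R_focus = 93, x_focus = 0.74)
  y <- ictalwave:::profile_model_predict(truth, x, R)
  prof <- structure(data.frame(roi = seq_along(x), distance_mm = x,
                               azimuth_deg = R, peak_dff = y),
                    class = c("event_profile", "data.frame"))
  fit <- fit_profile_model(prof)
  for (p in c("sigma", "lambda", "a", "R_focus", "x_focus"))
    expect_equal(unname(fit$par[p]), truth[[p]],
                 tolerance = 0.01 * abs(truth[[p]]) /
                   max(abs(truth[[p]]), 1e-9))
  expect_lt(abs(fit$par["b"] - truth$b), 0.01)
})

test_that("a flat profile is flagged degenerate with a = b", {
  prof <- structure(data.frame(roi = 1:10, distance_mm = seq(0, 2.7, 0.3),
                               azimuth_deg = seq(140, 0, length.out = 10),
                               peak_dff = rep(0.4, 10)),
                    class = c("event_profile", "data.frame"))
  fit <- fit_profile_model(prof)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$par["sigma"]))
  expect_equal(unname(fit$par["a"]), 0.4)
  expect_equal(unname(fit$par["b"]), 0.4)
})

test_that("generator events yield bimodal profiles with an LM peak", {
  path <- build_roi_path(default_geom$azimuth, default_geom$area,
                         default_geom$elevation, default_geom$focus_rc,
                         default_geom$pixel_pitch)
  mov <- interictal_movie(seed = 71, noise_sd = 0)
  prof <- extract_profile(mov, path, c(0, 0.5), smooth_frames = 1)
  lm <- prof$peak_dff[path$area == 2L]
  v1 <- prof$peak_dff[path$area == 1L]
  ## second local maximum inside LM, well above the inter-lobe trough
  expect_gt(max(lm), min(v1[v1 > 0]) * 1.5)
  imax_lm <- which.max(lm)
  expect_gt(imax_lm, 1)                      # interior peak, rising into LM
  ## V1/LM amplitude ratio near the planted factor of 8
  expect_equal(max(v1) / max(lm), 8, tolerance = 0.35)
  ## model fit reproduces the second local maximum in LM
  fit <- fit_profile_model(prof)
  pred <- fit$fitted
  lm_idx <- which(path$area == 2L & is.finite(prof$peak_dff))
  expect_gt(max(pred[lm_idx]), pred[min(lm_idx) - 2])
})

test_that("profile parameter recovery stays within 15% under noise", {
  ses <- render_retinotopy_session(default_geom, seed = 81)
  rmap <- map_retinotopy(ses)
  path <- build_roi_path(rmap$azimuth, default_geom$area,
                         default_geom$elevation, default_geom$focus_rc,
                         default_geom$pixel_pitch)
  p <- generator_defaults(); p$contiguity_hwhm_mm <- 0.6
  pars <- t(vapply(1:12, function(i) {
    mov <- interictal_movie(seed = 500 + i, jitter = FALSE, defaults = p)
    prof <- extract_profile(mov, path, c(0, 0.5))
    fit_profile_model(prof)$par
  }, numeric(6)))
  expect_lt(median(abs(pars[, "sigma"] - 25) / 25), 0.15)
  expect_lt(median(abs(pars[, "lambda"] - 0.6) / 0.6), 0.15)
})

test_that("a zero movie gives an all-zero profile and missing ROIs error out", {
  path <- build_roi_path(default_geom$azimuth, default_geom$area,
                         default_geom$elevation, default_geom$focus_rc,
                         default_geom$pixel_pitch)
  Z <- matrix_movie(matrix(0, 6, 64 * 64), 64, 64)
  prof <- extract_profile(Z, path, c(0, 0.1), smooth_frames = 1)
  expect_true(all(prof$peak_dff == 0))
  expect_error(fit_profile_model(prof[1:4, ]), "at least 8")
})
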