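## Multiplicative contiguity x homotopy model of the V1 -> LM activity profile.

#' Homotopy term: Gaussian falloff with retinotopic distance
#'
#' H(x) = exp(-(R(x) - R_focus)^2 / (2 sigma^2)); unitless in [0, 1], equal to
#' 1 where the retinotopic preference matches the focus and 0.5 at
#' |R - R_focus| = sigma * sqrt(2 ln 2).
#'
#' @param R retinotopic position(s), degrees.
#' @param sigma homotopy width in degrees (> 0).
#' @param R_focus retinotopic position of the focus, degrees.
#' @return numeric of the same shape as `R`.
#' @export
homotopy_term <- function(R, sigma, R_focus) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  exp(-(R - R_focus)^2 / (2 * sigma^2))
}

#' Contiguity term: flat-top falloff with cortical distance
#'
#' C(x) = (a - b) exp(-(x - x_focus)^4 / (lambda^4 / ln 2)) + b. The fourth
#' power gives a flat top; lambda is the half-width at half-maximum, i.e.
#' C(x_focus) = a and C(x_focus +/- lambda) = (a + b) / 2.
#'
#' @param x cortical position(s) along the profile, mm.
#' @param lambda half-width at half-maximum, mm (> 0).
#' @param a level at the focus (dF/F).
#' @param b floor level (dF/F).
#' @param x_focus cortical position of the focus, mm.
#' @return numeric of the same shape as `x`, in dF/F units.
#' @export
contiguity_term <- function(x, lambda, a, b, x_focus) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0", call. = FALSE)
  (a - b) * exp(-(x - x_focus)^4 / (lambda^4 / log(2))) + b
}

## model prediction at ROIs given a parameter vector
profile_model_predict <- function(par, distance_mm, azimuth_deg) {
  contiguity_term(distance_mm, par[["lambda"]], par[["a"]], par[["b"]],
                  par[["x_focus"]]) *
    homotopy_term(azimuth_deg, par[["sigma"]], par[["R_focus"]])
}

#' Extract the per-ROI activity profile of an event
#'
#' For each ROI along the path the pixel traces in a disk of the ROI radius are
#' averaged, and the profile value is the maximum of that mean trace within the
#' event window. A short boxcar smooth (default 5 frames) is applied to the ROI
#' trace first: the maximum of a raw noisy trace is biased upward by the noise,
#' which would inflate the fitted homotopy width, while the event time course
#' is smooth at the frame scale.
#'
#' @param dff a [dff_movie()].
#' @param path an `roi_path` from [build_roi_path()].
#' @param window numeric (t0, t1) event window in seconds.
#' @param smooth_frames boxcar length in frames applied to each ROI trace
#'   before the maximum; 1 disables smoothing.
#' @return data.frame of class `event_profile`: roi index, distance_mm,
#'   azimuth_deg, peak_dff (NA for ROIs fully outside the mask).
#' @export
extract_profile <- function(dff, path, window, smooth_frames = 5) {
  stopifnot(inherits(dff, "iw_movie"), inherits(path, "roi_path"))
  idx <- window_frames(dff, window)
  X <- movie_matrix(dff, idx)
  nr <- dim(dff$frames)[2]; nc <- dim(dff$frames)[3]
  rpx <- attr(path, "roi_radius_mm") / dff$pixel_pitch
  peaks <- vapply(seq_len(nrow(path)), function(i) {
    rc <- c(path$row[i], path$col[i])
    rows <- pmax(1, floor(rc[1] - rpx)):pmin(nr, ceiling(rc[1] + rpx))
    cols <- pmax(1, floor(rc[2] - rpx)):pmin(nc, ceiling(rc[2] + rpx))
    g <- expand.grid(r = rows, c = cols)
    keep <- (g$r - rc[1])^2 + (g$c - rc[2])^2 <= rpx^2 + 1e-9
    g <- g[keep, , drop = FALSE]
    inmask <- dff$mask[cbind(g$r, g$c)]
    if (!any(inmask)) return(NA_real_)
    g <- g[inmask, , drop = FALSE]
    pix <- (g$c - 1L) * nr + g$r
    tr <- rowMeans(X[, pix, drop = FALSE])
    if (smooth_frames > 1 && length(tr) >= smooth_frames)
      tr <- stats::filter(tr, rep(1 / smooth_frames, smooth_frames),
                          sides = 2)
    max(tr, na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(roi = seq_len(nrow(path)),
                       distance_mm = path$distance_mm,
                       azimuth_deg = path$azimuth_deg,
                       peak_dff = peaks),
            class = c("event_profile", "data.frame"))
}

#' Fit the six-parameter contiguity x homotopy model to a profile
#'
#' Least-squares fit of peak dF/F along the V1 -> LM path to
#' C(x) * H(R(x)), with parameters sigma (homotopy width, deg), lambda
#' (contiguity HWHM, mm), a (focus level), b (floor), R_focus (deg) and
#' x_focus (mm along the path). The amplitude lives entirely in C; H is
#' unitless. Bounded multi-start optimisation (nlminb) from a deterministic
#' set of stratified starting points plus a data-driven start at the profile
#' maximum; the best residual wins. ROIs are weighted equally.
#'
#' @param profile an `event_profile` (needs >= 8 ROIs spanning both areas, in
#'   practice >= 8 non-missing rows).
#' @param n_starts number of stratified starts (default 16).
#' @return object of class `profile_fit`: list with `par` (named parameter
#'   vector), `rss`, `fitted`, `profile`, `degenerate` flag and `n_starts`.
#' @export
fit_profile_model <- function(profile, n_starts = 16) {
  pr <- profile[is.finite(profile$peak_dff), , drop = FALSE]
  if (nrow(pr) < 8)
    stop("need at least 8 ROIs with finite profile values", call. = FALSE)
  y <- pr$peak_dff; x <- pr$distance_mm; R <- pr$azimuth_deg
  span <- diff(range(R)); plen <- max(x)
  if (stats::sd(y) < 1e-12 || span == 0) {
    par <- c(sigma = NA_real_, lambda = NA_real_, a = mean(y), b = mean(y),
             R_focus = NA_real_, x_focus = NA_real_)
    return(structure(list(par = par, rss = 0, fitted = rep(mean(y), nrow(pr)),
                          profile = pr, degenerate = TRUE, n_starts = 0),
                     class = "profile_fit"))
  }
  lower <- c(sigma = 1, lambda = 0.05, a = 0, b = 0,
             R_focus = min(R), x_focus = 0)
  upper <- c(sigma = 140, lambda = plen, a = 2 * max(y), b = max(y),
             R_focus = max(R), x_focus = plen)
  obj <- function(p) {
    names(p) <- names(lower)
    sum((y - profile_model_predict(as.list(p), x, R))^2)
  }
  imax <- which.max(y)
  starts <- list(c(sigma = 25, lambda = 0.6, a = max(y), b = min(y),
                   R_focus = R[imax], x_focus = x[imax]))
  ## stratified deterministic grid of additional starts
  sig0 <- c(10, 25, 60, 120); lam0 <- c(0.25, 0.5, 1, 2) * plen / 2
  k <- 0
  for (s in sig0) for (l in lam0) {
    k <- k + 1
    if (k > n_starts - 1) break
    starts[[k + 1]] <- c(sigma = s, lambda = min(l, plen),
                         a = max(y), b = 0.1 * max(y),
                         R_focus = R[imax], x_focus = x[imax])
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(stats::nlminb(st, obj, lower = lower, upper = upper,
                                  control = list(iter.max = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    stop("profile model fit failed from all starting points", call. = FALSE)
  par <- best$par; names(par) <- names(lower)
  fitted <- profile_model_predict(as.list(par), x, R)
  structure(list(par = par, rss = best$objective, fitted = fitted,
                 profile = pr, degenerate = FALSE, n_starts = length(starts)),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<profile_fit> degenerate (flat profile): a = b =",
        signif(x$par[["a"]], 4), "\n")
    return(invisible(x))
  }
  p <- x$par
  cat(sprintf(
    "<profile_fit> sigma %.1f deg | lambda %.2f mm | a %.3f | b %.3f | R_focus %.1f deg | x_focus %.2f mm\n",
    p["sigma"], p["lambda"], p["a"], p["b"], p["R_focus"], p["x_focus"]))
  cat(sprintf("  RSS %.4g over %d ROIs (%d starts)\n", x$rss, nrow(x$profile),
              x$n_starts))
  invisible(x)
}
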