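---
title: "Models and methods behind ictalwave"
author: "ictalwave authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ictalwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ictalwave` analyses widefield calcium-imaging movies of pharmacologically
induced focal epileptiform activity in mouse visual cortex, together with the
simultaneously recorded local field potential (LFP). This vignette explains
the models the package fits, the synthetic cortex it simulates, the defaults
it ships with and why, and what the package's tests do and do not establish.

## The scientific setting

A focal epileptic site in primary visual cortex (V1) produces two kinds of
events: brief interictal discharges (hundreds of milliseconds) and prolonged
seizures (many seconds) that propagate across cortex. Visual cortex is
retinotopically organised: each location prefers a position in the visual
field, and higher areas such as LM contain a mirrored copy of that map.
Locations in different areas that share a visual-field preference
("homotopic" locations) are preferentially interconnected. The package's
analyses are all built to separate two propagation routes: *contiguous*
spread, which falls off with cortical distance from the focus, and
*homotopic* spread, which falls off with retinotopic distance.

## The models fitted by the package

### Rank-1 standing wave

An event movie, arranged as a frames-by-pixels matrix $M$, is modelled as

$$ M = c \, m^\top + R, $$

a single time course $c(t)$ times a single spatial map $m(x)$ plus residuals.
`fit_standing_wave()` obtains the best least-squares rank-1 factorisation
from the leading singular triplet of $M$. Conventions: the map has unit
Euclidean norm (the scale lives in the time course), the time course is
nonnegative at its absolute peak, and variance explained is computed on the
raw, uncentred values over masked pixels,
$1 - \lVert R\rVert_F^2 / \lVert M\rVert_F^2$. No mean is subtracted, because
the model describes the movie itself rather than its anomalies; masked-out
pixels are excluded from all norms rather than zero-filled, which would bias
variance explained upward. `fit_fixed_map()` is the constrained variant used
for seizures: the map is frozen (typically to the interictal average) and
each frame's coefficient is the closed-form projection
$\langle m, f\rangle / \langle m, m\rangle$.

### Contiguity x homotopy profile model

Activity profiles along a path of regions of interest (ROIs) from the V1
focus into LM are fitted with a six-parameter multiplicative model,

$$ \hat y(x) = C(x)\, H(R(x)), \qquad
   H(x) = e^{-(R(x)-R_\mathrm{focus})^2 / 2\sigma^2}, \qquad
   C(x) = (a-b)\, e^{-(x-x_\mathrm{focus})^4 / (\lambda^4/\ln 2)} + b, $$

where $R(x)$ is the preferred azimuth at cortical position $x$. $H$ is
unitless in $[0,1]$ and carries the homotopy width $\sigma$ (degrees); $C$
carries the amplitude: $a$ is the level at the focus, $b$ the floor, and the
quartic exponent makes a flat top whose half-width at half-maximum is exactly
$\lambda$ (mm). The amplitude is placed entirely in $C$ because the product
is otherwise only identified up to a swap of scales. The second, smaller
activity lobe in LM arises where $C$ has already decayed to $b$ but $H$
returns to 1, so the V1/LM amplitude ratio of the fitted curve is $a/b$.
Retinotopic distance uses azimuth only: the ROI path is constructed inside an
elevation iso-band, so elevation is constant along it by design.

Fitting is bounded nonlinear least squares (`nlminb`) from 16 deterministic
starts (one data-driven at the profile maximum plus a stratified
$\sigma \times \lambda$ grid); the quartic exponent creates flat regions in
the objective, and the multi-start is what makes the fit reliable. ROIs are
weighted equally; the fit has no information about ROI area. A profile with
zero variance is returned as a degenerate fit ($a=b$, $\sigma$ undefined)
rather than an error.

### Delay to seizure invasion and the speed regression

A pixel is *recruited* when its maximal dF/F during the seizure exceeds 30%
of the peak recorded at the focus. Its *delay to invasion* is the first time
its fluorescence reaches 60% of its own maximum, linearly interpolated
between the bracketing frames (sub-frame precision at 35-70 Hz) and measured
from the electrographic onset. Because the criterion is relative to the
pixel's own maximum it is invariant to per-pixel amplitude differences.

`speed_regression()` averages per-pixel delays across seizures first and
regresses binned delays (0.1 mm distance bins, bin means, unweighted ordinary
least squares) on cortical distance; speed is 1/slope. Binning keeps the fit
from being dominated by the outermost distance ring, where most pixels live.
The residuals of that distance-only fit are then correlated with retinotopic
(azimuthal) distance from the focus: a positive correlation is the signature
of the homotopic route, and the package's simulations reproduce the contrast
(large positive correlation with the route enabled, near zero with it
disabled).

### Oscillation phase analysis

Ictal 6-11 Hz oscillations are isolated with a 4th-order Butterworth
band-pass applied forward-backward (zero phase - a one-way filter would add
a frequency-dependent delay that is exactly the quantity under study), then
converted per pixel to the analytic signal $f + i\,\mathcal H(f) = A e^{i\varphi}$.
The focus-referenced phase-delay map takes the circular mean of the wrapped
per-frame phase differences and divides by the *measured* mean instantaneous
angular frequency of the focus, not a nominal band centre, because the
frequency drifts within a seizure. Lags live in $(-T/2, T/2]$, with exactly
half a period mapping to $+T/2$. Pixels whose mean amplitude falls below 5%
of the focus amplitude are excluded from phase statistics.

Spiral waves are detected as phase singularities: the winding number of the
wrapped phase differences around each elementary 2x2 pixel loop, with
$\pm 1$ flagged as pinwheel cores and checked against their local amplitude
minimum. The sum of interior charges always equals the boundary winding
number, which the test suite asserts on constructed fields.

## The synthetic cortex

No public dataset accompanies this problem, so the package carries a
generator whose planted parameters every analysis must recover. It simulates:

* **Geometry** (`make_geometry()`): a 64 x 64 grid at 0.05 mm/pixel (3.15 mm
  field of view) holding a 2.2 mm-wide V1 spanning 140 degrees of azimuth and
  a mirrored ~1 mm LM, with elevation spanning 60 degrees along the
  orthogonal axis. The focus sits in V1 at 93 degrees azimuth. The geometry
  is parametric (axis-aligned area bands), not atlas-derived: registration to
  a reference atlas is a separate problem the package does not address.
* **Interictal events**: exact standing waves - the contiguity x homotopy
  footprint (peak 1.25 dF/F, $\lambda$ = 0.9 mm, isotropic 25-degree
  homotopy kernel in azimuth and elevation, V1/LM ratio 8) times a
  difference-of-exponentials time course (rise 50 ms, decay 300 ms, matching
  the 0.5 s median duration; the exact shape is otherwise unconstrained).
  Event centres jitter around the focus with an RMS radius of 0.32 mm.
* **Seizures**: a brief interictal-amplitude standing wave at onset (seizures
  begin like interictal events) followed by a travelling front. Each pixel
  turns on with a sigmoid (time constant 0.12 s) at its planted delay, whose
  60%-of-plateau crossing falls exactly at that delay, and carries a 6-11 Hz
  oscillation whose phase lag grows at 0.002 s per second of invasion delay.
  The delay field combines a 0.48 mm/s contiguous front, a homotopic jump
  that seeds the LM location retinotopically matched to the focus after 4 s,
  and a linear retinotopic slowdown of 0.008 s/degree. The slowdown term is
  what makes delay depend approximately linearly on *both* cortical and
  retinotopic distance; a jump alone produces only a localised LM trough,
  whose residuals correlate weakly with retinotopy no matter how strong the
  route is. The jump and slowdown defaults were fixed by forward simulation
  of the planted field, before any recovery was attempted, so that the
  planted structure carries a strong delay-distance correlation, an unbiased
  speed readout and a large residual-retinotopy correlation simultaneously.
* **LFP** (`render_lfp()`): a sharp 75 ms negative deflection at each onset,
  plus for seizures a sustained slow deflection and the 6-11 Hz oscillation,
  on Gaussian background noise. The electrographic seizure discharge ends
  0.8 s before the fluorescence-defined offset; this also compensates the
  slow tail of the analytic envelope used by the offset detector.
* **Retinotopy sessions**: contrast-reversing gratings at four azimuths
  (5 s, 2 Hz reversal) driving each pixel at the 4 Hz second harmonic with a
  Gaussian position tuning of width 25 degrees and peak response 0.04 dF/F -
  visual responses are deliberately ~30x smaller than epileptiform events.
* **Noise**: i.i.d. Gaussian per pixel-frame, default SD 5% of the event
  peak. This is the simplest model that exercises every estimator; it has no
  photon statistics, no spatial correlation, no hemodynamic contamination
  and no motion. Consequently the recovery studies demonstrate correctness
  of the estimators, not robustness to every artefact of real recordings.

The field of view, footprint scale and noise level jointly set the
signal-to-noise regime of the standing-wave fits; they were chosen once, by
forward calculation of the planted rank-1 energy against the noise floor, to
put synthetic events in the ~94-95% variance-explained regime typical of
high-quality widefield recordings of such events.

## Event detection on the LFP

The trace is resampled to 100 Hz (chained FIR decimation). Candidate onsets
are local maxima of the absolute first derivative above 3 standard deviations
of the derivative over the full trace. The *plain* SD is used deliberately:
the events themselves inflate it, so the threshold self-scales with event
density, whereas a robust (MAD-based) scale tracks the noise floor and fires
on ~0.2 Gaussian-noise maxima per second regardless of SNR, which no
amplitude margin can fix. On a pure-noise trace the detector therefore
reports the derivative's threshold crossings - reproducing that false-alarm
behaviour is part of the test suite. The absolute derivative is used (the
deflections are negative-going, but polarity is recorded rather than
assumed). Candidates within an ongoing event, or within a 300 ms refractory
window of the previous onset, are discarded. An event ends when the
magnitude of the analytic signal of the <5 Hz low-passed trace stays below
its median + 1 robust SD for at least 200 ms. Classification splits
log-durations by an exhaustive two-class minimum-within-variance threshold,
falling back to a fixed 2 s with a warning when the class medians are within
a factor of 4 (not clearly bimodal). There is no manual review stage:
everything is deterministic and reproducible.

## Numerical choices worth knowing

* Percentiles (the dF/F baseline, variance-explained bands) use linear
  interpolation between order statistics (R's type 7), stated explicitly for
  reproducibility.
* Coordinates are (row, column), 1-based in R; distances in mm via the pixel
  pitch. Movies are stored (time, rows, cols).
* `extract_profile()` smooths each ROI trace with a 5-frame boxcar before
  taking its maximum. The maximum of a raw noisy trace is biased upward by
  roughly twice the trace's noise SD, which acts like an additive offset the
  multiplicative model cannot represent and stretches the fitted $\sigma$;
  the event time course is smooth at the frame scale, so the boxcar removes
  most of the bias at negligible cost. ROI radius 0.1 mm and spacing 0.15 mm
  balance disk-averaging (which widens the narrow LM lobe) against per-ROI
  noise.
* The ROI path marches the gradient of a 3x3 median-smoothed azimuth map
  (raw per-pixel gradients are noise-dominated), constrained to a +/-5 degree
  elevation iso-band; of the two gradient directions, the one whose ray
  reaches LM is taken, and inside LM the sign flips so the march keeps moving
  outward across the mirrored map.
* The shared tuning width of the retinotopy fit is a 5-60 degree grid search
  in 1-degree steps; per-pixel centres are found on a 1-degree grid and
  refined by parabolic interpolation, giving sub-degree recovery on clean
  data.
* Movies are written as multi-page 32-bit float TIFF. The writer stores
  values in [0, 1], so frames are min/max-normalised on disk with the affine
  transform recorded in the JSON sidecar; round trips are exact to float32
  relative precision.
* TIFF masks, CSV traces and JSON sidecars/fit bundles are all plain text or
  standard formats readable outside R.

## Open choices and their resolutions

* Whether the V1-to-LM "line" should be a geodesic of the gradient field or
  a straight segment: the package marches the gradient field; on the
  generator's linear maps the two coincide.
* Whether delays are averaged across seizures before or after the
  regression: averaged first, per pixel; the per-seizure alternative is a
  one-line change on the returned delay maps.
* The LM onset delay of interictal events is not constrained by data; the
  homotopic jump delay is an explicit, documented generator parameter.
* The "pacemaker epoch" of a seizure (how long the focus leads the
  oscillation) has no canonical definition. `pacemaker_epoch()` evaluates,
  per oscillation cycle, whether at most 5% of oscillating pixels lead the
  focus, requiring pixels to have oscillated for a full cycle already
  (freshly invaded pixels carry the band-pass filter's step response, whose
  phase is meaningless). Under per-pixel noise the strict 5% criterion is
  conservative; treat the estimate as a lower bound.

## Problem sizes

The simulation studies used by the tests and the benchmark script run at the
generator's native scale: 64 x 64 pixels at 35 Hz, 50 interictal events for
the standing-wave study, 30 events for the profile study, 20 seizures of 8 s
for the invasion study, and 30 minutes of 1 kHz LFP for the detection study.
The full test suite completes in about a minute on one core.

## Known limitations

* The generator's noise model is white; real widefield noise is spatially
  and temporally correlated (hemodynamics, vasculature, motion), and the
  recovery figures here will be optimistic relative to such data.
* Area segmentation is not performed: area labels come from the generator or
  from a user-supplied label image.
* Registration, photobleaching and motion correction are assumed to have
  been applied upstream; the readers only verify shape consistency.
* The profile model is one-dimensional along the ROI path; no full-image 2-D
  variant is provided.
* Rank-1 is the only decomposition offered; higher-rank or ICA/NMF
  alternatives are out of scope.
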