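---
title: "Foveolar sampling analysis: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveolar sampling analysis: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveolar)
```

The package analyses cell-resolved visual sampling in the human foveola, the
rod-free central ~1 degree of the retina where cone density peaks. Its input
world is that of adaptive-optics scanning laser ophthalmoscopy (AOSLO):
labelled cone-center coordinates on a calibrated master image, per-trial
stimulus trajectories registered to that image, and 4AFC orientation
responses to dark Snellen-E optotypes delivered on the scanning raster.
Everything downstream — density landmarks, cone light capture, drift
statistics, acuity thresholds — is computed from those three tables, so the
entire pipeline can also run end-to-end on the package's synthetic
generators.

All positions are in arcmin in the image frame (origin top-left, x
rightward, y downward; 1 deg = 60 arcmin), densities in cones/deg^2, angles
in degrees, measured counterclockwise on the screen so that screen-up is
+90.

## Cone density landmarks

Cone patches come from a Voronoi tessellation of the cone centers
(`tessellate()`, backed by deldir). Cells are clipped to the image
rectangle: leaving boundary cells unbounded would poison every
nearest-neighbour area sum, and when all cones across the image are
labelled, clipping is the best available estimate of the true patch area.
The pixel-resolved density map (`density_map()`) assigns to each pixel
center `k / sum(area of the k nearest cones)` with `k = 150` by default;
nearest is plain Euclidean distance from pixel center to cone center, ties
broken by cone index. The map can be computed on a decimated grid
(`stride`) for speed; `foveolar_landmarks()` then refines the peak on the
full grid in a small window around the coarse optimum.

Three landmark quantities derive from the map:

* **PCD** (peak cone density): the map maximum and its pixel; ties are
  resolved in row-major order and flagged `degenerate_tie`.
* **CDC** (cone density centroid): the density-weighted centroid of the
  pixels at or above the 80th percentile of map values (`top_fraction =
  0.20`). The percentile is taken over pixel values of the whole map, not
  over cones, because the CDC is defined on the pixel-resolved map. The CDC
  is the anchor for all directional statistics; it is far more stable than
  the PCD, which rides on a single pixel.
* **ICD / Nyquist limit**: assuming a perfect hexagonal mosaic at density
  rho (per deg^2), the spacing is `ICD = sqrt(2 / (sqrt(3) rho))` and the
  row-spacing resolution limit is `N = (sqrt(3)/2) ICD`. The row-spacing
  constant is an argument of `nyquist_limit()` rather than a hard-coded
  value.

A boundary caveat that matters for testing: for a pixel within the pooling
radius of the image edge (about 6.4 lattice spacings for k = 150), the
nearest-150 sum includes clipped boundary cells, and the estimate is
unbiased only where the boundary cuts the mosaic "fairly" (between lattice
rows). The hexagonal-lattice oracle tests therefore evaluate bands whose
pooling disks touch only row-parallel boundaries; on jittered, gradient
mosaics the effect is sub-percent and spatially smooth, and the CDC (an
interior, weighted centroid) is insensitive to it.

## Retinal image model

The stimulus is a standard 5x5-construction Snellen E (stroke = gap = one
fifth of letter height), rendered as a binary decrement bitmap at the raster
pixel scale (0.1 arcmin/px, i.e. 600 px/deg) with the gap quantized to whole
pixels, as a raster display forces. The retinal image is the convolution of
that bitmap with a diffraction-limited point spread function: the incoherent
monochromatic Airy pattern `[2 J1(v) / v]^2` for the configured wavelength
and pupil (defaults 788 nm, 7 mm). No Stiles–Crawford apodization and no
residual aberrations are modelled; adaptive-optics correction is treated as
ideal.

Numerical choices: the kernel is sampled at pixel centers, truncated at the
radius enclosing 99% of the Airy pattern's energy (computed from the
analytic encircled-energy curve `1 - J0^2 - J1^2`, about 17 first-zero
radii), and renormalized to unit sum; supports below 4 Airy radii are
refused. Convolution is exact zero-padded FFT convolution. Working in
decrement space (background = 0, full darkness = 1) makes zero padding the
physically correct "background continues" boundary condition, and the
bitmap is padded by the kernel support so no blurred energy is clipped —
energy is conserved to float precision.

`stimulus_contrast()` reports the contrast of the blurred dark letter
against the uniform infrared background. Two metrics are provided. The
default is Michelson contrast, `d / (2 - d)` where `d` is the maximum
decrement: with this definition the 18 and 36 arcsec gap stimuli under
788 nm / 7 mm optics come out at 0.60 and 0.81, matching the 0.61 / 0.80
contrast pair quoted for exactly this protocol; the Weber decrement
(`d` itself, 0.75 / 0.90 for the same stimuli) is available via
`metric = "weber"`. The anchor pair is what arbitrated the default.

## Cone light capture and sampling density

Each cone gets a circular Gaussian acceptance aperture whose diameter is
48% of the mean distance to its Delaunay neighbours (the natural reading of
"all of its neighbours" once a tessellation exists). The profile width maps
diameter to Gaussian sigma via FWHM = diameter (`sigma = d / 2.3548`),
the common convention in AO microstimulation work; the factor is an
argument. Activation of a cone at a given stimulus position is the
aperture-weighted mean decrement — the integral of profile x image over the
integral of the profile — so it is 1 exactly when the aperture is filled
with full stimulus darkness, 0 with no stimulus, and invariant to any
rescaling of the profile. Integrals are evaluated on a grid supersampled 4x
relative to the image pixels, out to 3 sigma, with bilinear interpolation of
the decrement map; this keeps pixel-quantization error below the 1e-6 level
probed by the translation-equivariance tests.

The **sampling cone density** of a frame is the number of cones whose
activation exceeds a threshold (default 0.01 — effectively "touched by the
blurred stimulus"; the threshold is exposed because the boundary between
touched and untouched is a modelling choice, not physics) divided by the
summed Voronoi areas of those cones. A frame with no interacting cone is
flagged undefined rather than zero. `trial_sampling_series()` evaluates
every frame in the stimulus-on window and summarizes the trial by the
median over defined frames.

## Drift metrics

Drift length is the concatenated vector sum of frame-wise displacements
inside the 500 ms stimulus window — a closed loop keeps its full path
length — and drift velocity divides by the window duration. Direction
statistics use the net onset-to-offset vector: theta_retina in retinal
coordinates, and theta relative to a landmark as the signed angle between
the drift vector and the onset-to-landmark line (0 = toward, 180 = away,
positive counterclockwise). The tuning ratio is the relative frequency of
drifts within +-45 degrees of the landmark direction over the mean of the
other three quadrants, with half-open bins `[-45, 45)` etc.; trials with
zero net displacement or onset at the landmark are excluded from
directionality and logged. Circular non-uniformity uses the native Rayleigh
test with the standard approximation
`p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))`.

Microsaccade detection is a median-based velocity-threshold detector in the
Engbert–Kliegl style (5-sample moving-window velocities, per-axis threshold
at lambda = 6 median-based SDs, minimum duration 6 ms), with two
adaptations: 3-point central differences fill the velocity estimate at the
two samples nearest each trace end, so ballistic events at the window edges
are not invisible; and the per-axis threshold is floored at 120 arcmin/s
(2 deg/s) because slow drift can have nearly constant velocity — zero
median-based variance — while real microsaccades peak well above a couple
of deg/s. Trials with a detected event overlapping the stimulus window, or
with a sampling gap above 50 ms (blink surrogate), are excluded.

The one-SD isoline area (ISOA) of a point cloud is computed from a
bivariate Gaussian kernel density estimate (Silverman's rule-of-thumb
bandwidth per axis) on a 0.1-arcmin grid: the contour level is chosen so
the cells above it hold 68.27% of the discretized probability mass, and the
area is the count of those cells times the cell area, summing disjoint
lobes. Bandwidth, mass level, and grid step are arguments. The KDE
bandwidth inflates the area of a tight Gaussian cloud by roughly
`(1 + h^2 / sigma^2)`; at n = 2000 points this is ~4%, well inside the 10%
tolerance the closed-form calibration test uses.

Sampling gain is the trial's maximum sampling density over its onset
density. The *potential* gain — not defined by a formula in the source
protocol — is interpreted as the density-map value at the CDC over the
onset density: the most the eye could have gained by re-centering the
stimulus on its anatomical density center. A PCD-referenced variant is a
one-line substitution via the landmark argument.

## Psychophysics

`quest_run()` implements the Watson–Pelli QUEST staircase on log10 gap
size: a Gaussian prior on threshold (SD 0.5 log10 units, centered on 40
arcsec), the QUEST Weibull likelihood (beta = 3.5, delta = 0.01, gamma =
0.25 for 4AFC), next stimulus at the posterior mode, stimulus sizes
quantized to whole raster pixels (6 arcsec at 0.1 arcmin/px). These
internals are not reported for the original protocol; the defaults above
are the package's documented choice and all are arguments. Five 20-trial
runs are pooled (~100 trials) and `fit_psychometric()` fits a
maximum-likelihood cumulative Gaussian on log10 size with guess rate fixed
at 0.25 and lapse bounded in [0, 0.06], reporting the threshold at 62.5%
correct — the midpoint between guessing and perfect performance. The
bootstrap CI (500 nonparametric resamples by default) is optional so
simulation studies can skip it. The sigmoid family is the package's choice
where the original analysis delegated to an external fitting tool; the fit
is deliberately pluggable through its parameters rather than through
multiple families.

Note a deliberate asymmetry: QUEST's internal Weibull places trials near
its own 72% point, while the fitted cumulative Gaussian defines the
threshold at 62.5%; recovery is therefore validated end-to-end (staircase +
fit), where a 24-arcsec synthetic observer is recovered within +-2 arcsec
in >= 90% of seeded sessions, rather than by equating the two estimators.

## Synthetic generators

The generators define the study conditions for every statistical test:

* **Mosaics** (`generate_mosaic()`): hexagonal lattice at the peak density
  `rho0` (default 14,000 cones/deg^2, inside the 10,700–17,000 range
  reported for human foveolae), radially warped so the cumulative cone
  count matches an isotropic exponential density decline
  `rho(r) = rho0 exp(-g r)` (default g = 0.02 per arcmin), with Gaussian
  positional jitter scaled to the local spacing (default 12%). The
  exponential form is adequate for landmark-recovery tests at foveolar
  scale; it is not a fitted anatomical model.
* **Drift traces** (`generate_drift_trace()`): 30 Hz cumulative random
  walks over a 1 s trial with a 500 ms stimulus window; gamma step lengths
  (shape 2) with a per-trial lognormal scale multiplier (sdlog 0.45),
  calibrated so the median windowed path length is ~6.5 arcmin with a
  2.5–17 arcmin spread — the drift statistics of foveolar fixation — rather
  than emulating any physiological self-avoiding-walk model. Directional
  bias draws each step's direction from a von Mises distribution aimed at
  the target *from the current position* with concentration kappa; the
  closed-loop re-aiming mirrors the visual-feedback account of drift
  control and, unlike a fixed start-to-target bearing, does not overshoot
  the target when the path length exceeds the starting distance. Optional
  single-frame 30-arcmin ballistic excursions emulate microsaccades and are
  labelled for recall tests.
* **Sessions** (`generate_session()`): QUEST-driven gap sizes, per-trial
  traces starting near the PRL and biased toward the CDC, and responses
  from a synthetic observer. By default the observer's true threshold is
  tied to the eye's Nyquist limit (`alpha = 0.84 N`, the reported ratio of
  human thresholds to the row-spacing limit under 788 nm testing), so
  denser synthetic eyes resolve smaller optotypes — the qualitative
  density–acuity coupling.

What the generators do *not* emulate — AOSLO image formation and noise,
stabilization artifacts, torsion, cone labelling errors, physiological
drift microstructure above 30 Hz — bounds what green tests mean: they
validate the estimators against known ground truth under idealized
sampling, not the instrument chain.

## Problem sizes and determinism

Defaults are sized for interactive use and continuous testing: synthetic
fields of 16–24 arcmin (1,000–2,500 cones), density maps on stride-4 grids
with full-grid landmark refinement, 200-seed recovery studies for the
staircase pipeline, 20 seeds for CDC recovery, 1,000–10,000 draws for the
Monte Carlo calibrations. Every generator is a deterministic function of
(parameters, seed); the statistical tests fix their seeds and test bands
chosen from the analytic values, not from observed outputs.

## Known limitations

* Clipped Voronoi patches bias nearest-k density within a pooling radius of
  the image edge (discussed above); an optional `margin` excludes edge
  pixels from the map but does not de-bias the pooling itself.
* The aperture model ignores the Stiles–Crawford effect, photopigment
  optical density, and temporal integration; activation is proportional to
  geometrically captured contrast decrement only.
* The ISOA depends on the KDE bandwidth; areas from different bandwidth
  rules are not comparable. The default is recorded in every result object.
* `rvonmises()` uses the Best–Fisher rejection sampler; extreme
  concentrations (kappa > 1e6) are unnecessary here and untested.
* The Rayleigh p approximation is accurate for n >= 10; the implementation
  refuses n < 5.
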