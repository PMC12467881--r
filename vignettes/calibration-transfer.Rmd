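---
title: "Calibration transfer for cross-instrument LIBS classification"
author: "libsbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration transfer for cross-instrument LIBS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Laser-induced breakdown spectroscopy (LIBS) reads out the elemental
fingerprint of a sample from the emission lines of a laser-generated
plasma. Combined with a classifier it can discriminate visually similar
medicinal plant materials — here the three Akebia-type stem slices
(Mutong, Chuan-mutong, Guan-mutong), of which Guan-mutong carries
nephrotoxic aristolochic acids and must never be substituted for the
others.

A classifier trained on one spectrometer usually collapses on data from
another. Two instruments differ in spectral range, resolution, detector
response and noise: a broadband CCD fiber-optic spectrometer
(190–1100 nm, 0.2–0.3 nm resolution, sensitivity rising toward the
infrared) and an echelle/ICCD system (200–850 nm, 0.01–0.02 nm
resolution, UV-weighted response with periodic order-overlap ripple)
report very different intensity patterns for the same plasma. `libsbridge`
implements a calibration-transfer pipeline that makes a model trained on
the low-resolution instrument usable on high-resolution spectra:

1. **SC — spectral correction.** Both instruments measure a radiometrically
   certified standard lamp. The ratio of the certified curve to the
   measured curve gives each instrument's wavelength-dependent correction
   $R(\lambda) = I_{\mathrm{ref}}(\lambda) / I_{\mathrm{meas}}(\lambda)$,
   the reciprocal of its sensitivity up to the lamp's arbitrary global
   scale. The transfer function $R_{H/L}(\lambda) = R_H(\lambda) /
   R_L(\lambda)$ then maps a high-resolution measurement onto the
   low-resolution instrument's intensity scale: since a measurement is
   source times sensitivity, $I_H \cdot R_H / R_L = \mathrm{source} \cdot
   \eta_L$, exactly what the training instrument would have recorded. The
   direction of the ratio matters; the package fixes it by this derivation
   and verifies it with a simulator round trip (the opposite convention
   fails that test). Correction is restricted to 350–850 nm, the overlap
   of the lamp's certified range with both detection ranges.
2. **FS — feature selection.** Classification runs on peak features, not
   full spectra. A base set of emission-line peaks is detected on the
   training instrument, and additional discriminative wavelengths are
   ranked by the one-way ANOVA F statistic and added incrementally until
   test accuracy peaks.
3. **PP — post-processing.** Abnormal test spectra (weakly coupled shots,
   continuum surges) are removed unsupervised with DBSCAN before
   evaluation, using the K-distance graph to choose the radius.

## Preprocessing

Raw low-resolution acquisitions are averaged in blocks of consecutive
shots (`averageBlocks`, typically 4) to raise signal-to-noise, then
smoothed with a Savitzky–Golay filter (`savgolSmooth`). High-resolution
spectra are accumulated on-chip over several shots and are neither
averaged further nor smoothed. Both datasets are finally max–min
normalized per spectrum, $y = (x - \min x) / (\max x - \min x)$, with the
spectrum's global extrema as the scalars, so every normalized spectrum
spans exactly [0, 1]. A constant spectrum is a degenerate-input error,
never a silent NaN.

Two ordering decisions matter:

* **Correct before normalizing.** Normalization destroys the absolute
  scale that the response correction operates on. A useful corollary,
  verified as a test invariant: because normalization rescales per
  spectrum, the pipeline is invariant to any global scale in $R$ — only
  the *shape* of the lamp curve matters.
* **The 1500-count threshold precedes normalization.** Peak selection and
  ANOVA candidate pools use a minimum class-mean intensity of 1500
  detector counts; a normalized spectrum never exceeds 1, so the
  threshold is meaningful only on pre-normalization intensities.

The Savitzky–Golay defaults are window 5, order 3. On the low-resolution
grid (0.111 nm per pixel) that is a 0.55 nm aperture: wide enough to cut
white-noise variance roughly in half, narrow enough that 0.28 nm FWHM
lines keep well above the 1500-count threshold. An 11-point window — a
2.4 nm aperture on this grid — attenuates such lines about six-fold,
pushes the weakest listed lines (V I 526.61) below the threshold and
merges the C-N band head into its shoulder, so it was rejected. Edge
handling fits the truncated polynomial at the boundaries (no padding), so
polynomials up to the filter order are reproduced exactly everywhere and
the filter is linear.

## Response estimation details

* The measured lamp is aligned onto the certified grid by linear
  interpolation (`interpAlign`; piecewise linear, no extrapolation).
* Division floor: measured points at or below $10^{-6} \times
  \max(\mathrm{measured})$ are masked and refilled by interpolating
  $\log R$ (responses are positive and roughly exponential in shape, so
  log-space interpolation avoids overshoot); more than 20% masked points
  aborts with an error.
* The ratio is denoised by default (3-point median, then a
  Savitzky–Golay fit over a ~1 nm window). The window is an order of
  magnitude narrower than the ~8 nm echelle ripple period, so genuine
  ripple in the high-resolution response — which must be corrected, since
  it is equally present in the measured spectra — survives smoothing,
  while lamp shot noise does not. The flag `smooth = FALSE` disables this
  for exact algebraic work.

## Feature machinery

* **Peak definition.** A base feature is a strict local maximum of a
  class-mean spectrum over a 7-pixel window (±0.33 nm at the
  low-resolution sampling — about one resolution element) exceeding the
  intensity threshold; detections from different classes within half a
  window merge onto the strongest pixel. O and H lines are excluded as
  atmosphere-dominated.
* **Cross-instrument matching.** Instruments disagree on absolute
  wavelength by 0.05–0.3 nm. For each reference feature, the nearest
  strict local maximum within ±0.3 nm (widened by half a grid step to
  absorb sampling discretization) is taken, provided it rises at least 5
  scaled MADs above the window median — a prominence floor that stops
  noise wiggles from being "matched" when no line is present. Exact
  distance ties resolve to the lower wavelength. Unmatched spectra fall
  back to the intensity at the nominal wavelength, and per-feature match
  rates are reported.
* **ANOVA ranking.** For a candidate wavelength with $N$ spectra in $k$
  classes, $F = \frac{SSB / (k-1)}{SSW / (N-k)}$ with the usual between-
  and within-class sums of squares. $F$ is invariant to common affine
  transforms of a candidate's intensities, so the ranking does not depend
  on whether normalized or raw values enter the computation. Degenerate
  cases are explicit: zero within-class variance with distinct means
  ranks first ($F = \infty$); all-equal data gives $F = 0$.
* **Incremental selection.** Ranked candidates are appended one at a time
  — skipping any within one grid step of an existing feature, the
  deduplication that in practice removes the ranked wavelengths sitting
  on already-selected peaks — with the forest retrained and test accuracy
  recorded at every step. The returned set maximizes accuracy; ties go to
  the smaller set.

## Classification

A random forest of 500 Gini-split trees with minimum leaf size 20 (the
tuned values for this task), `sqrt(p)` features per split, plain
bootstrap. Single-instrument evaluation splits each class 70:30 in
acquisition order (first block trains, last block tests — no shuffling,
so train and test come from different sample slices); cross-instrument
evaluation trains on all low-resolution and tests on all high-resolution
spectra. Vote ties resolve to the lowest class index, and a fixed seed
makes fits and predictions bit-identical.

## Post-processing

DBSCAN runs on the same feature matrix the classifier consumes (values in
[0, 1] after normalization, so no re-scaling is applied by default; a
full-spectrum or z-scored variant is a configuration choice away). With
`minPts = 15`, a point is core when at least 15 points (itself included)
lie within `eps`; clusters grow by density reachability, border points
are retained, and only noise is removed. The radius comes from the
K-distance graph at `k = minPts`: the sorted 15th-neighbour distances are
lightly smoothed and the elbow is automated as the point farthest below
the chord joining the curve's endpoints. A maximum-curvature rule was
tried first and tended to fire between individual outliers deep in the
sparse tail; the chord criterion lands where the dense bulk ends, which
is what a practitioner picks by eye. `eps` can always be overridden
manually.

## What the simulator emulates — and what it does not

No measured Akebia spectra are distributed, so the package ships a
two-instrument simulator that reproduces the statistical structure the
pipeline relies on:

* **Emission model.** Gaussian lines specified by integrated area, pixel
  integration across detector bins (the difference of Gaussian CDFs at
  pixel edges), instrumental FWHM broadening, and a bundled line table:
  20 atomic/molecular peaks plus shaded combs of weak lines degrading
  violet-ward from the C-N band heads (381–388 nm) and from Fe I
  402.96 nm. The combs blend into unresolved shoulders at low resolution
  but resolve into individual narrow lines on the echelle — which is
  exactly why ANOVA finds "new" discriminative wavelengths inside those
  bands that are not peaks of the low-resolution spectra.
* **Class structure.** Three class profiles share the line table and
  differ by ±0.3 log-offsets on the CN, Fe and K line groups;
  sample-to-sample variability is log-normal (σ = 0.15 per line per
  sample slice, 10 slices per class) and shot-to-shot energy jitter
  log-normal (σ = 0.05). Between-class contrast therefore concentrates in
  the 381–388, 402–403 and 766–769 nm regions, and spectra clump by
  sample slice.
* **Instruments.** Low-res: 190–1100 nm, 8192 points, FWHM 0.28 nm,
  response rising into the IR. High-res: 200–850 nm, 86400 points, FWHM
  0.018 nm, response falling from the UV with 15% sinusoidal ripple of
  8 nm period. Both FWHMs sit inside the stated resolution bands and both
  grids sample at roughly two pixels per FWHM — the Nyquist-style
  sampling real spectrograph designs aim for. Coarser, one-pixel-per-FWHM
  grids alias sampled peak heights by a random per-line factor of up to
  two, a distortion that no intensity correction can undo and that would
  measure grid artefacts rather than response transfer. Registration
  shifts are drawn from [0.05, 0.3] nm per instrument; noise is additive
  Gaussian plus a 2% signal-proportional term.
* **Abnormal spectra.** A configurable fraction of the test set is
  corrupted and flagged for ground truth: *collapse* outliers scale the
  emission by U(0.05, 0.2) with lines below 450 nm suppressed by an extra
  square root of that factor (a weakly coupled shot yields a cooler
  plasma that starves the hotter UV emission disproportionately — a pure
  global scaling would be erased by per-spectrum normalization and is not
  what bad shots look like); *surge* outliers add a broad Gaussian
  continuum of 30–80% of the spectrum maximum at a random position.

Not emulated: plasma physics (Saha–Boltzmann populations, self-absorption,
Stark broadening), matrix effects, wavelength drift *within* a dataset,
detector nonlinearity and saturation. Passing the acceptance suite
therefore demonstrates that the pipeline recovers response-and-resolution
induced distortions under realistic noise and outlier contamination; it
does not certify performance on effects outside the simulator's scope,
and the simulator's effect sizes are free parameters, so simulated
accuracies are not calibrated to any particular measured campaign.

## Problem sizes and reproducibility

The acceptance suite runs the full study at 3 classes × 500 spectra per
instrument (10 sample slices per class), 10% planted outliers in the test
set, over 10 seeds — large enough for stable orderings between protocols,
small enough to run on a single CPU in minutes. Unit and integration
tests use reduced replicates of the same structure. Every stochastic
stage (simulation, bootstrap, selection) keys off one seed; identical
configuration and seed reproduce run reports byte for byte.

## Known limitations

* Resolution mismatch is handled by band-robust feature matching, not by
  deconvolution; features whose low-resolution values blend several
  unresolved lines keep an instrument-dependent component even after
  correction.
* The DBSCAN feature space and scaling follow the classifier's feature
  matrix by default; on differently scaled inputs the automated elbow
  should be checked against the plotted K-distance curve.
* Incremental selection uses test accuracy as its objective, mirroring
  the feature-count sweep it implements; for unbiased error estimates an
  untouched validation instrument would be required.
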