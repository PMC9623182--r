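---
title: "Methods: visible-band phenotyping and nitrogen estimation in uavpnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visible-band phenotyping and nitrogen estimation in uavpnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

uavpnc implements the plot-level workflow by which crop nitrogen status is
estimated from nothing more than a UAV digital camera: visible-band
vegetation indices and canopy morphology are extracted from an RGB
orthomosaic (DOM) and a digital surface model (DSM), then regressed on
plant nitrogen content (PNC, % of dry mass). This vignette is the
package's own account of the procedure, its assumptions, its tunable
parameters and the places where the design was genuinely open.

## The measurement model

All layers are assumed co-registered on one grid (the workflow that
produces DOM and DSM pins both to surveyed ground control points, so no
reprojection step is provided). Pixels are addressed `(row, col)` from the
top-left; the affine transform maps pixel centres to world coordinates and
is restricted to axis-aligned grids. Membership of a pixel in a plot is
decided by its centre point — a deterministic rule that an exhaustive
point-in-polygon loop can verify, which is exactly how the test suite
checks it.

**Chromaticities and indices.** Digital numbers are reduced to
chromaticities `r = R/(R+G+B)` etc., removing overall brightness so that
indices respond to colour composition only; the test suite asserts this
scale invariance directly. Ten indices (R, G, B, GRRI, GLA, GLI, GRVI,
VARI, EXG, NDI) form a fixed registry whose order also serves as the
deterministic tie-break in feature selection. Two registry entries deserve
a note: GLA is implemented exactly as registered, `(2g−r+b)/(2g+r+b)`,
although it differs from GLI only in the sign of `b` — the definition is
preserved as published rather than "corrected"; and GRRI is `r/g` on
chromaticities, which by scale invariance equals the common R/G form.
Pixels with a zero band sum or a zero denominator (e.g. VARI where
`g + r = b`) are flagged invalid rather than allowed to produce NaN, and
per-plot means report the count of valid pixels they used.

**Plot aggregation.** Index values are computed per pixel and then
averaged per plot over *all* plot pixels by default; restricting the mean
to vegetation pixels is available as an option (`mask_vegetation`).
Whether plot statistics should be vegetation-masked is not settled
practice; the unmasked default makes the index a property of the whole
plot (canopy plus visible soil), which is what a nadir camera actually
sees, and the option exposes the alternative for sensitivity analysis.

**Plant height.** `CHM = DSM_stage − DSM_bare`, clamped at zero because
negative canopy heights are physically meaningless artefacts of DSM noise.
Plot height is the mean CHM over the plot's vegetation-mask pixels,
reported in cm; "average height" could equally be read as an all-pixel
mean, so a `p90` percentile statistic is provided as an alternative for
sensitivity analysis. If the mask covers no plot pixel the all-pixel mean
is used with a warning.

**Canopy coverage.** The UAV route computes EXG on chromaticities and
thresholds it globally with the maximum inter-class variance (Otsu)
criterion; the published description calls this step the "bimodal method"
for the DOM and "maximum inter-class variance" for the ground photos — one
criterion, two call sites, and one implementation here. The Otsu contract
is fixed precisely: a 256-bin histogram over the input range, the cut
maximising `w0 w1 (µ0 − µ1)²`, the smallest maximiser on ties, and
`value > threshold` as foreground. Constant input is a degenerate-input
error. The implementation is vectorised but the suite checks hard
equality against a naive 255-cut loop on every kind of input it can
think of.

**VCEA (ground-photo coverage).** The reference coverage comes from
white-box ground photos processed in three stages: an HSI pre-filter
(hue 60–180°, saturation ≥ 0.1) keeps green candidates; an EXG Otsu
threshold separates vegetation from soil; connected components smaller
than 25 px are removed (the "morphological threshold"), which is what
eliminates weed specks. The published operator sequence leaves two things
open. First, the parameter values: the hue window, saturation floor and
minimum component area used here are stated defaults, all overridable.
Second, the population on which the EXG threshold is estimated: uavpnc
estimates it on the whole frame interior rather than on the HSI
candidates alone, because once the hue filter has removed soil the
candidate histogram is single-class and a threshold estimated inside it
would split vegetation against itself. HSI itself is the standard
geometric conversion; hue is undefined at zero saturation and flagged.

**Canopy volume.** `CV = CC × H` (cm) compresses horizontal and vertical
canopy extent into one number; because `CC ≤ 1`, `CV ≤ H` always.

## Models and evaluation

The trial's structure fixes the data split: replicates 1 and 3 calibrate
(32 plots), replicate 2 validates (16 plots). Three estimators sit behind
one interface: ordinary least squares with intercept; k-nearest-neighbour
regression with uniform weights and Euclidean distance on features
z-scored with *training* means and SDs (k = 5 by default — the method is
standard but k and the scaling are not published, so both are explicit and
configurable); and a random forest with 500 trees and `ceiling(p/3)`
candidate features per split, seeded, with training rows canonically
ordered before fitting so the bootstrap is invariant to row order.

Feature sets are named exactly: `"VIs"` is the top-5 indices by absolute
Pearson correlation with PNC, computed on the *training* partition only so
that feature selection cannot leak validation information (whether the
original selection used all data is unknowable from the text; the
leakage-free choice is the conservative one and may account for small
differences). `"MPs"` is {H, CC, CV}; `"VIs+MPs"` their 8-feature union;
single-MP sets are available by name.

Evaluation: `R² = 1 − SS_res/SS_tot` (validation R² may be negative),
`RMSE` in %PNC units, and `NRMSE = RMSE / mean(observed) × 100`. The
normalisation by the mean rather than the range is deliberate: dividing
representative published RMSE/NRMSE pairs gives back the stage's mean PNC
(e.g. 0.30/0.0899 ≈ 3.3), while range normalisation would give a number
some 40% larger. Correlation screening reports the two-sided t-test
p-value with `df = n − 2` and flags significance at α = 0.01; no
multiple-testing correction is applied, matching the original analysis.

## What the synthetic trial emulates — and what it does not

The generator reproduces a 48-plot potato trial: a density zone (3 levels
× 2 varieties × 3 replicates = 18 plots), a nitrogen zone (4 × 2 × 3 =
24) and a potassium zone (2 × 1 × 3 = 6), plots of 32.5 m² on a regular
grid. Per-plot truth is drawn per stage (S1 tuber formation, S2 tuber
growth, S3 starch accumulation):

* **PNC** comes from treatment-level means — monotone in nitrogen level,
  mildly decreasing in planting density, a small variety offset — plus
  Gaussian plot noise. Published pooled statistics give stage envelopes
  (e.g. S1 PNC in [2.09, 4.50] % with mean 3.21) but no per-treatment
  means, so the effect sizes are generator defaults, not field estimates.
* **H and CC** are linear in the standardised PNC with stage-dependent
  target correlations r = 0.7 / 0.6 / 0.5 at S1 / S2 / S3 — morphology
  decouples from nitrogen as the season advances — plus independent noise.
  All three variables are affinely shrunk into their stage envelopes;
  affine maps preserve Pearson correlation, so range enforcement cannot
  distort the coupling (the suite verifies the mean sample correlation
  over 200 seeds and the degenerate r = 1 case exactly).
* **Rendering.** Soil is a brown DN anchor (140, 95, 75) with per-channel
  Gaussian jitter (SD 8 DN by default); plants are overlapping disks
  (nominal radius 0.20 m) whose green chromaticity increases affinely with
  the plot's PNC (`g = 0.50 + 0.035 (PNC − stage mean)`). Disks are placed
  — and the last disk trimmed pixel by pixel — until the plot's vegetation
  count equals `round(true_CC × plot pixels)` exactly, after which
  `true_CC` is back-filled from the final mask: mask and truth agree to
  the pixel, so coverage benchmarks carry no packing stochasticity. The
  DSM is a smooth terrain surface plus the plot height (cm → m) over
  vegetation pixels, plus optional noise (SD 0.01 m by default). Ground
  photos use the same colour model at 4× resolution inside a white 1.3 m
  frame. A `weeds` flag adds green blobs in aisles and sub-threshold
  specks to exercise the VCEA area filter.
* **Senescence.** At S2/S3 a fraction of vegetation pixels (0.04 / 0.12)
  is drawn from a yellow anchor whose EXG falls below the vegetation/soil
  threshold. These fractions were calibrated so the stage ladder of
  coverage-extraction error on synthetic scenes reproduces the published
  stage-wise CC accuracy ladder (RMSE roughly 0.02 / 0.05 / 0.08 at
  S1/S2/S3) in rank and rough magnitude — this is the mechanism behind
  the "early stages extract better" behaviour the tests assert.

Deliberately **not** emulated: BRDF, shadows and illumination gradients;
3-D plant architecture (canopies are flat-topped disks); weather and
mixed-pixel effects beyond DN jitter; and — importantly — any plot-level
canopy-colour variation unrelated to nitrogen. The default keeps the
greenness a noiseless affine function of PNC at plot scale (a per-plot
nuisance term `g_plot_sd` exists but defaults to 0), which guarantees the
index signal is recoverable by construction. The consequence is that
index-based model accuracy on synthetic scenes is an *upper bound*: plot
means average thousands of pixels, DN jitter cancels, and validation R²
values near 1 say nothing about field accuracy, where unmodelled colour
variation is the dominant error source. Passing tests therefore certify
the machinery — segmentation, zonal statistics, height differencing, the
modelling chain — not field-level predictive skill.

## Numerical choices and degenerate inputs

* Otsu ties go to the smallest maximising cut; constant inputs error.
* A weak-bimodality warning (separability `σ_b²/σ² < 0.75`) flags scenes
  — e.g. bare soil — where a global threshold is not meaningful, and a
  near-empty foreground (< 1%) is also flagged.
* Rasters: 8-bit DN and binary masks round-trip bit-exactly through TIFF;
  metric layers are stored as 32-bit floats rescaled to the unit interval
  with scale/offset in a JSON sidecar (round-trip error below 1e-4 m on
  terrain-scale values), and the affine lives in a world file, exact to
  1e-9. Nodata cells survive the round trip as NA and are excluded from
  every per-plot statistic.
* Requested coverage above 0.99 is an infeasible-packing error rather
  than an endless placement loop.
* Master seed 20190418 by default; every operation takes an explicit
  seed, and the pipeline derives per-stage seeds deterministically from
  one master seed, so identical configurations produce byte-identical
  output files.

## Problem sizes used by the test suite

The suite renders full 48-plot scenes (1220 × 740 px at 5 cm resolution)
where the scene itself is under test, and single-plot scenes (170 × 140
px) for Monte-Carlo recovery runs: 100 seeded plots for height recovery,
50 regression seasons for linear recovery, 20 rendered seasons for the
directional comparisons, 1000 random histograms for the Otsu oracle.
These sizes keep the complete suite in the minutes range on one CPU while
leaving the estimates' Monte-Carlo error well inside the asserted margins.

## Known limitations

* Only axis-aligned affines are supported; rotated or reprojected inputs
  must be resampled upstream.
* The replication split is fixed by design; no cross-validation or
  uncertainty intervals on R² are provided.
* With 16 validation plots the sampling standard deviation of R² at a
  true R² of 0.8 is about 0.1 — single-season validation R² values are
  individually noisy, which is why the directional tests compare medians
  over many seeded seasons rather than single runs.
* The synthetic benchmark certifies correctness of the extraction and
  modelling machinery, not transferability to field imagery (see above).
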