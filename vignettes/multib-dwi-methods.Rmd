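---
title: "Multi-b DWI models, phantom design and diagnostic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-b DWI models, phantom design and diagnostic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbDWI)
```

mbDWI implements the quantitative chain used to separate tumour
progression from pseudoprogression on multi-b-value diffusion MRI:
three decay models inverted voxel by voxel, a lesion ROI measurement
protocol, and the diagnostic statistics run on the per-lesion values.
This vignette records the modelling assumptions, the numerical choices,
and what the synthetic phantom cohort does and does not establish.

## Decay models

All models are written as ratios against the measured unattenuated
signal, so `S(0)` is never a free parameter:

* monoexponential, `S(b)/S(0) = exp(−b·ADC)`;
* biexponential (intravoxel incoherent motion),
  `S(b)/S(0) = (1−f)·exp(−b·D) + f·exp(−b·(D*+D))`;
* stretched-exponential, `S(b)/S(0) = exp(−(b·DDC)^α)`.

Diffusion coefficients are stored in mm²/s — the physically meaningful
unit, with typical brain-tissue values near 1×10⁻³ — and multiplied by
10³ only in display tables, matching the "×10⁻³" convention of the
clinical literature. The biexponential fast compartment is written with
the `(D* + D)` exponent; a `biexpForm = "conventional"` switch in
`FittingConfig()` selects the `exp(−b·D*)` variant found in much of the
IVIM literature. The two differ only by a reparameterisation of `D*`
(the difference is absorbed into the `D*` estimate), but the default is
kept explicit rather than silently normalised. In the stretched model
the exponent applies to the product `b·DDC`; the constraint
`α ∈ (0, 1]` makes α = 1 the monoexponential limit and smaller α more
intravoxel heterogeneity.

The default acquisition scheme is the 12-point protocol (0, 10, 20, 40,
60, 70, 80, 100, 200, 400, 800, 1000 s/mm²). Its dense sampling below
100 s/mm² is what makes the perfusion compartment estimable at all.

## Fitting strategy

**ADC** defaults to the two-point closed form
`ln(S(0)/S(1000))/1000`, mirroring the conventional two-b DWI protocol
that clinical ADC maps are built from, even when all 12 points are
available; a log-linear least-squares over all b-values is available via
`adcMethod = "loglinear"`.

**Biexponential.** The full four-parameter problem is notoriously
ill-conditioned, so the fit is segmented: (1) log-linear fit of the
points with `b ≥ 200` s/mm² — the first b-value beyond the
perfusion-sensitive regime in the default scheme — yields `D` and an
intercept; (2) `f = 1 − exp(intercept)`, clipped to [0, 1]; (3) a
bounded 1-D least squares on the full curve estimates `D*` with `D` and
`f` held; (4) a bounded Levenberg–Marquardt refinement over all three
parameters, initialised from (1–3), is run by default. Bounds are wide
enough to contain reported tissue values with margin:
`D ∈ (10⁻⁶, 5×10⁻³)`, `D* ∈ (10⁻⁴, 5×10⁻¹)` mm²/s, `f ∈ [0, 1]`, and
`D* ≥ D` is enforced (also at the class level) to keep the two
compartments identifiable. Noise-free round trips recover parameters to
~10⁻¹⁴ relative error; under Rician noise at SNR 50 the median fitted
`D` error is below 1% while `D*` remains the least stable parameter —
its recovery is asserted only in median and only loosely.

**Stretched.** Bounded Levenberg–Marquardt on
`(DDC, α)`, DDC initialised from the two-point ADC and α at 0.8, with
`DDC ∈ (10⁻⁶, 10⁻¹)` mm²/s, `α ∈ (0.01, 1]`.

Solver tolerances are `ftol = ptol = 10⁻¹²` with at most 200
iterations. Degenerate curves (non-positive or non-decaying signal) are
flagged `converged = FALSE` with boundary or NA parameters; in
`fitVolume()` this policy is per voxel — pathological voxels land in the
quality map and never abort a volume. Voxels are mutually independent,
so maps do not depend on traversal order.

## The phantom cohort

`paperLikePreset()` encodes the emulated study: 22 progression and 18
pseudoprogression lesions whose per-lesion parameter means and SDs
follow the published group summaries, sampled on the 12-point scheme.
Per-subject truths are drawn independently per parameter from normals
truncated to each parameter's valid range (with `D*` redrawn until
`D* ≥ D`); no between-parameter covariance is imposed because none is
reported — a documented simplification.

Each lesion is a homogeneous ellipsoid (semi-axes 1.9 × 1.9 voxels
in-plane, 2.2 slices; 2.5 × 2.5 × 4 mm voxels) whose central-slice
cross-section (~56 mm²) sits inside the 45–65 mm² ROI band of the
emulated protocol, embedded in a white-matter-like background fixed at
`D = 0.8×10⁻³` mm²/s, `f = 0.05` (α ≈ 0.95 behaviour) — arbitrary but
constant. Noise is Rician, the magnitude-MRI standard:
`observed = sqrt((clean+g₁)² + g₂²)` with `g₁, g₂ ~ N(0, S(0)/SNR)`,
SNR defined at b = 0 in the lesion and defaulting to 50.

**Lesion signal is the equal blend of the biexponential and stretched
decays** implied by the subject's six drawn parameters. A single decay
law cannot carry independent ground truth for all six parameters: if
voxels decay purely biexponentially, the groups' DDC contrast collapses
(the stretched fit then reads DDC mostly off `f` and `D*`, and the
noise-free between-group DDC difference falls below the between-subject
spread), leaving the cohort unable to exhibit the six-parameter
separation it is meant to emulate. The blend — half the water pool
showing perfusion-driven biexponential behaviour, half anomalous
heterogeneous diffusion — lets every drawn parameter leave a signature
in the curve while remaining a physically interpretable mixture. The
consequence is deliberate model mismatch: no model's fit can equal its
drawn parameters exactly, so each subject's model-consistent "truth" is
defined as the noise-free best fit of that model to the generating
curve (`derivedTruths()`), and recovery at SNR 50 is judged against
those. Drawn values still set the between-group directionality, which
the fitted cohort reproduces for all six parameters.

What passing phantom tests do **not** show about real data: lesions here
are internally homogeneous (no texture, necrosis or partial volume),
noise is spatially white, there is no motion, eddy-current or
susceptibility artefact, and reader disagreement is a random mask
perturbation rather than anatomical judgement. The phantom validates
the estimator chain, not the clinical effect sizes.

## ROI protocol

Measurements follow the emulated reading protocol: the three consecutive
axial slices (third array dimension, 1-based indices) carrying the most
in-mask voxels are selected — ties broken toward the inferior-most
triple — and each parameter map is averaged over the in-mask,
non-missing voxels on those slices. The protocol's "three ROIs measured
three times" is operationalised as three repeats of the
selection-and-mean procedure, averaged; repeats are identical for a
deterministic mask and differ when per-repeat masks from
`simulateSecondReader()` are supplied. That simulator models a second
reader as a small random translation plus random boundary
erosion/dilation, constrained to ≥ 50% overlap with the original.
Masks are strictly binary (nonzero = in-ROI). ROI areas are reported as
mean per-slice in-plane area and warned about outside 45–65 mm².

## Statistics

* **Group comparison** uses the pooled-variance (Student) t test with
  `df = n₁ + n₂ − 2`. The choice is empirical: recomputing t from the
  published per-group n/mean/SD reproduces the published statistics
  only under the pooled form. `summaryTTest()` exposes the
  summary-statistics route directly.
* **Normality** screening is Lilliefors-corrected Kolmogorov–Smirnov
  (estimated-parameter null), via `nortest`; zero-variance samples are
  flagged degenerate rather than tested.
* **Agreement** is ICC(2,1) — two-way random effects, absolute
  agreement, single measures — with the McGraw–Wong F-based 95% CI, and
  banded poor/fair/moderate/good/excellent at 0.20/0.40/0.60/0.80. The
  form is fixed, not tuned: published ICCs are not reproducible without
  the raw readings. Bland–Altman limits are bias ± 1.96·SD of paired
  differences.
* **ROC** follows the Mann–Whitney convention (ties count ½), computed
  by the rank-sum identity so the AUC equals exhaustive pair counting
  exactly. Orientation is auto-selected so AUC ≥ 0.5 and recorded as a
  direction flag. Candidate cutoffs are midpoints between consecutive
  distinct values plus ±∞; the Youden-optimal cutoff breaks ties toward
  higher specificity. CIs use the DeLong placement-value variance,
  truncated to [0, 1].
* **DeLong comparisons** of two markers on the same subjects use the
  placement-value covariance. Orientation is an explicit argument, not
  inferred: folding both markers toward AUC ≥ 0.5 inside the test
  collapses its size under the null (measured type-I error ~0.003
  instead of 0.05), so `buildReport()` passes each marker's recorded
  ROC direction and the test itself stays unfolded, holding its nominal
  size in calibration.
* **No multiple-testing correction** is applied across the six
  parameters or fifteen AUC pairs, matching the emulated analysis; this
  is recorded in the report metadata.

## Problem sizes

The test suite exercises: 1000-parameter noise-free round trips
(tolerance 10⁻⁶ relative), 500 small ROC instances against the
brute-force oracle (exact), 1000 null replicates for DeLong size
(n = 100 per class, acceptance band 0.03–0.07), 100 random two-rater
matrices against an ANOVA-decomposition ICC oracle (10⁻⁶), 500 noisy
voxel fits for median-bias bounds, and the full 22 + 18 cohort at
SNR 50 end to end. The whole suite runs in well under a minute on one
core; the end-to-end cohort takes a few seconds because lesions are
~30 voxels each — large enough for ROI averaging to behave, small
enough to keep simulation cheap.

## Known limitations

`D*` is fundamentally ill-conditioned at clinical SNR; treat its maps
and group statistics with caution. The phantom draws parameters
independently within group, which overstates how separable parameters
are relative to correlated real lesions. The Youden cutoff is an
in-sample optimum with the usual optimism; no cross-validation is
provided. Motion/eddy correction, denoising and registration are out of
scope — inputs are assumed co-registered, as are maps and masks.
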