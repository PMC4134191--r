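---
title: "Quantifying intratumoral metabolic heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral metabolic heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorhet)
```

## The measurement problem

Glucose uptake inside a tumor is not uniform. Hypoxic subregions shift
toward glycolysis and import more glucose analogue than the surrounding
tumor tissue, so the spatial texture of a metabolic image carries biology.
Two obstacles stand between a reconstructed image and an honest
heterogeneity number:

1. **Delineation.** The tumor boundary must come from the image itself,
   reproducibly, not from a hand-drawn contour.
2. **Partial-volume contamination.** Finite scanner resolution (0.5–0.7 cm
   FWHM for a clinical PET system) blurs background into the tumor rim,
   depressing edge-voxel intensities and inflating any within-ROI spread
   statistic with an artifact that has nothing to do with biology.

The pipeline addresses both: a gradient-based delineation produces an edge
ROI (**ROI-E**), a metric contraction by the resolution distance produces
the conservative interior ROI (**ROI-C**), and heterogeneity is summarized
by the **coefficient of variation** `CV = SD / mean` of the voxel
intensities (sample SD, `n − 1`; the CV of a constant region is 0, and the
CV is invariant under intensity rescaling, so it compares tumors imaged at
different uptake levels). For multi-channel fluorescence scans, a hypoxia
channel drives hotspot detection and the glucose channel is quantified
inside the transferred masks; **fold enrichment** is
`mean(sub) / mean(whole)`.

## Gradient-based delineation

`segment_gradient_edge()` casts `n_rays` (default 500) quasi-uniform
Fibonacci-sphere rays from a seed point, samples the (optionally
pre-smoothed) volume by trilinear interpolation at a quarter-voxel pitch,
and places the boundary on each ray at the maximum of the *descending*
directional gradient, ties broken nearest the seed (the conservative
choice: a smaller ROI biases toward tumor-only tissue). The per-ray radii
are rendered as a star-convex region and regularized by metric closing
(default 2 mm); the output is the face-connected component containing the
seed. Non-star-convex lesions are out of scope by construction, and no
parity with any commercial edge-detection product is claimed — the
algorithm operationalizes the published *principle* (boundary at the
spatial-gradient maximum) in an auditable form.

**Curvature correction.** For a 1D step edge blurred with a Gaussian of
scale $\sigma$, the gradient extremum sits exactly at the step. On a
blurred *sphere* of radius $R$ it does not: the surface curvature shifts
the radial gradient maximum inward by $\approx 2\sigma^2/R$ (about 1.3 mm
for $R = 10$ mm at FWHM 6 mm — more than a voxel on a millimetre grid).
Each ray therefore estimates its local edge scale $\hat\sigma$ from the
half-maximum width of the gradient peak (width $= 2\sqrt{2\ln 2}\,
\hat\sigma$ for a Gaussian-derivative peak) and reports the fixed point of
$\hat r = r_{\text{raw}} + 2\hat\sigma^2/\hat r$, i.e.
$\hat r = \tfrac12\bigl(r_{\text{raw}} + \sqrt{r_{\text{raw}}^2 +
8\hat\sigma^2}\bigr)$. On blurred spherical phantoms this recovers the
true radius within one voxel along every axis; on sharp edges
$\hat\sigma \approx 0$ and the correction vanishes. It can be disabled
(`curvature_correction = FALSE`), and the uncorrected detector is exposed
as `profile_edge_radius()` so its 1D behaviour is testable against a
brute-force finite-difference argmax.

## Metric contraction on anisotropic grids

`contract_roi()` keeps exactly the in-mask voxels whose centers lie at
Euclidean distance `>= distance_mm` from the nearest voxel center outside
the mask. Distances are physical: the squared Euclidean distance transform
(a separable lower-envelope algorithm, compiled) takes the per-axis pitch,
so a 5 mm contraction strips different voxel-layer counts along 4.7 mm and
3.3 mm axes. Three conventions are fixed once and asserted everywhere:

* **Voxel-center distances**, not surface distances — well-defined on any
  anisotropic grid and directly checkable by an all-pairs oracle.
* **Closed threshold** (`>=`), which makes distance 0 the exact identity.
  The behaviour of voxels at exactly the contraction distance is not
  observable-data-constrained; the closed choice is flagged for
  sensitivity analysis, and the validation suite avoids probing distances
  that coincide exactly with attainable voxel-pair distances, where the
  keep/drop decision of *any* implementation would hinge on float
  rounding.
* **The grid border counts as outside**: a mask clipped by the field of
  view erodes at the clip too, since those edge voxels suffer the same
  partial-volume corruption.

A contraction that removes every voxel (lesion smaller than twice the
distance) is a warning, not an error — small lesions legitimately vanish
from ROI-C and the run report records it.

Rasterization is voxel-center point sampling throughout (a voxel belongs
to a shape iff its center is inside, closed inequality), which makes every
mask brute-force checkable. The worked consistency example: a 5 cm-radius
sphere rasterized at 1 mm, contracted by 0.5 cm, leaves an ROI whose
equivalent-sphere radius $(3V/4\pi)^{1/3}$ is 4.53 cm — 4.5 cm within a
voxel of discretization.

## The digital phantom generator

No raw imaging data accompany the analyses this package implements, so the
generator is a first-class module: every downstream stage is validated on
scenes with known truth. A phantom is a piecewise-constant scene —
constant background, ellipsoidal tumor, spherical hotspots at
`tumor_level × multiplier` — rendered by voxel-center sampling, then
blurred with a Gaussian PSF (sigma $= \text{FWHM}/(2\sqrt{2\ln 2})$ per
axis, converted to voxels through the spacing, kernel sampled to
4 sigma and normalized to unit sum, constant padding at the background
level so the grid border introduces no artificial gradients), then
degraded with noise. Ground-truth masks are the *pre-blur* supports:
anatomy is sharp, only the image is blurred, as in real acquisition.
Noise is either constant-SD Gaussian or proportional (SD = fraction ×
local intensity); negatives are clipped at zero (tracer concentrations are
non-negative) and the clipped fraction is recorded on the volume. All
randomness flows from one explicit integer seed per call —
identical spec + seed is bit-identical — with per-channel seeds derived
deterministically from the spec seed.

What the phantoms deliberately do **not** model: reconstruction physics
(attenuation, scatter, randoms, iterative-reconstruction texture),
pharmacokinetics of probe uptake, or non-ellipsoidal lesion shapes.
Passing the suites shows the *estimators* are correct under blur and noise
of the stated magnitude, not that any specific scanner is simulated.

### Standard suite conditions

The validation suites run on one fixed set of conditions,
`standard_suite_spec()`: a 48³ grid at 1 mm isotropic pitch; a spherical
tumor of radius 10 mm at intensity 1 on a 0.1 background (4:1 contrast for
the noiseless segmentation variant); an optional single hotspot occupying
10% of the tumor volume (radius $10 \cdot 0.1^{1/3} \approx 4.64$ mm)
with its center jittered uniformly within a 2 mm ball per seed; PSF FWHM
6 mm; 5% proportional noise. Rationale: the blur-to-tumor ratio
(FWHM/diameter = 0.3) reproduces the difficult clinical regime; the
compact grid keeps a full multi-seed suite to seconds per phantom;
geometry-faithful constructors (`pet_geometry_spec()`: 128×128×47 at
4.7×4.7×3.3 mm; `fmt_geometry_spec()`: 0.25 mm slice pitch, 225 mm³
tumor) are provided for realism checks. Neither modality's noise level is
published for the workflow this package implements, so 5% proportional
noise is a design choice, stated once here and not tuned.

Two suite-level design points deserve emphasis:

* **Enrichment null condition.** The recovery arm (multiplier 2.0, blur,
  noise) checks that fold enrichment survives the PSF: the measured fold
  stays within 15% of the no-blur mixture value
  $m / (1 - f + m f) = 1.818$ (multiplier $m = 2$, volume fraction
  $f = 0.1$) because the hotspot's partial-volume loss and the whole
  tumor's edge loss largely cancel in the ratio. The *null* arm
  (multiplier 1.0) runs noise-only, without blur: under blur, the ratio
  interior/whole is $\approx 1/(1 - f_t)$ where $f_t$ is the
  edge-loss fraction — about 1.3 for this geometry — for *any* correct
  estimator; that is partial-volume physics, not estimator bias. The
  noise-only null isolates what it is meant to test: that noise alone
  creates no spurious enrichment (measured fold = 1.00 ± 0.01 across
  seeds).
* **CV monotonicity.** With matched seeds, the in-tumor CV is strictly
  increasing in hotspot multiplier {1.0, 1.5, 2.0, 3.0} (the hotspot adds
  a variance component growing as $(m-1)^2$), and a 9-vs-7 batch of
  hotspot-positive vs hotspot-free phantoms separates by pooled t-test at
  p < 0.05 — the synthetic analogue of grouping tumors by detectable
  hypoxia and comparing their glucose-uptake CVs.

## Histograms, group comparison, reporting

ROI histograms use uniform left-closed right-open bins anchored at zero,
so binning is reproducible and independent of the data range; counts sum
to the ROI voxel count. The default clinical-unit bin width (1000, native
intensity units) matches convention for activity-concentration histograms;
it is fully configurable, and the phantom-scale analyses use widths
commensurate with their intensity scale. Group CV comparisons use
Student's pooled two-sample t-test (the variant named by the workflow this
implements) with Welch's available behind `var_equal = FALSE`; the
degenerate both-groups-constant case reports t = 0, p = 1 rather than an
error. CVs are *printed* at 2 decimals in tabular output to match
reporting convention; all comparisons use full precision. The median of an
even-count sample is the midpoint of the central pair.

## IHC scoring

`positive_pixel_score()` classifies 0–255 grayscale pixels (darker =
stronger stain) as positive at brightness ≤ 220, with weak/medium/strong
classes at (175, 220], (100, 175], ≤ 100 — explicit stand-ins for
proprietary commercial defaults. Per region, expression =
mean inverted brightness of positive pixels × positive-area percentage on
the **0–100 scale** (a deliberate, documented unit choice: it puts scores
in the range where published per-marker means of roughly 50–170 land
under 0–255 intensities and fractional areas). Per marker,
`marker_heterogeneity()` reduces ≥ 2 region scores to mean/SD/CV. Stain
separation (color deconvolution) is out of scope; fixtures are
single-channel. Region *selection* is an input — a pathologist chooses the
regions; the module scores what it is given.

The synthetic IHC fixture draws intensity and positive-area from lognormal
distributions (strictly positive, right-skewed, CV-parameterizable): for
target mean $m$ and CV $c$, $\sigma_{\log}^2 = \log(1 + c^2)$ and
$\mu_{\log} = \log m - \sigma_{\log}^2/2$. The product of two independent
lognormals has $CV^2 = (1+c_i^2)(1+c_a^2) - 1$, which the round-trip test
exploits.

### Reference tables and a documented inconsistency

Two small summary tables ship as CSVs: a 16-cell per-tumor × per-marker
IHC heterogeneity panel (HIF-1α, LDH-M, CAIX, ATP5β; two hypoxia-positive
and two hypoxia-negative xenograft tumors, 20 regions each) and a
four-patient FDG-PET descriptive-statistics table for ROI-C. They serve as
consistency inputs: every IHC cell satisfies
`round(SD/mean, 2) == printed CV` (16/16), and the separation of
hypoxia-positive from hypoxia-negative CVs holds marker-by-marker for
HIF-1α, CAIX and ATP5β, while LDH-M's four CVs sit in a narrow band
(0.044–0.080) — similar across status groups. In the PET table, patients
2 and 4 are internally consistent (0.15, 0.09), while patients 1 and 3
are **not**: their printed SD/mean give 0.11 and 0.35 against printed CVs
of 0.12 and 0.37. The plausible explanations — CV computed on a different
ROI, or from pre-rounding values — cannot be distinguished from the table
itself. The package defines `cv = sd/mean`, documents the discrepancy
here, and asserts consistency only for the consistent rows.

## Numerical choices and degenerate inputs

* Distance-transform distances are exact squared sums per axis; the
  contraction threshold is applied to distances, with the closed
  convention above.
* Blur kernels are renormalized after sampling, so interior total
  intensity is conserved to ~1e-6 relative; `fwhm = 0` bypasses the
  convolution entirely (exact identity).
* Rays that find no descending gradient (flat profiles) are tolerated up
  to 10%; beyond that the segmentation errors out ("flat image"). Below
  it, failed rays borrow the boundary radius of their nearest valid
  direction.
* Grid agreement for ROI transfer and channel sets is 1e-6 mm — NIfTI
  headers store geometry as 32-bit floats, so round-tripped spacings agree
  to ~1e-7 relative, comfortably inside the gate, and genuinely different
  grids fail it loudly. No resampling is ever performed; mismatches are
  errors.
* An ROI whose mean is ≤ 0 has no meaningful CV: reported `NA` with a
  warning.
* Empty hotspot lists, empty enrichment tables, and missing group
  comparisons (fewer than 2 tumors in a group) are valid outcomes,
  reported as such.

## Known limitations

* The delineation is star-convex about the seed: lobulated or annular
  lesions will be circumscribed, not traced.
* The curvature correction assumes a locally spherical edge; strongly
  prolate lesions at coarse resolution retain a residual bias (fractions
  of a voxel in the tested regime).
* Phantoms validate estimator behaviour under idealized blur + noise;
  reconstruction texture, motion, and uptake physiology are not emulated,
  so real-data CVs will carry variance components the suites do not
  exercise.
* The hotspot detection threshold is explicitly configurable because the
  thresholds used with real probes are instrument- and study-specific;
  defaults (0.5 × in-mask max, ≥ 1 mm³, face connectivity) are starting
  points, not calibrated values.
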