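---
title: "Fractal radiomics for molecular prediction in low-grade glioma: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal radiomics for molecular prediction in low-grade glioma: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliofract)
```

## The problem

Diffuse low-grade gliomas (WHO grade II–III) are classified by molecular
alterations — IDH mutation, 1p/19q co-deletion, ATRX and TERT mutations, and
MGMT promoter methylation — that today require invasive tissue sampling.
`gliofract` implements a radiomic pipeline that predicts these alterations
from routine multimodal MRI (T1, post-contrast T1, T2, FLAIR) plus a tumor
sub-region segmentation in the BraTS convention (necrosis/non-enhancing
core, edema, enhancing tumor). Its distinctive ingredient is a family of
*fractal and multi-resolution fractal* texture characterizations of the
tumor, whose contribution is quantified by an ablation comparison: every
model is fit with and without the fractal-derived features.

Because the clinical imaging cohorts behind such studies cannot be shipped
with a package, `gliofract` includes a first-class synthetic phantom module
that generates 3D textured tumor phantoms with known ground truth, so every
stage — texture estimation, feature catalogue, nested cross-validation,
ablation, survival analysis — is validated end to end against constructions
with known answers.

## Fractal texture characterizations

Three local estimators are mapped over the tumor: each axial in-tumor voxel
receives the estimate from a window centered on it (default side 17;
windows reaching past the volume edge are filled by reflection), producing
three derived volumes tagged `PTPSA`, `MBM`, and `HE`.

**PTPSA (piecewise triangular-prism surface area).** The intensity patch is
treated as a height field. At cell size $s$ the corner heights of each
$s\times s$ cell form four triangles with the bilinear center height, and
the total triangulated area $A(s)$ is computed for $s \in \{1,2,4,8\}$
(sampling points spaced $s$, so the window side minus one must be divisible
by the largest step — hence the odd default window). The fractal dimension
is $D = 2 - \mathrm{slope}\,[\log A(s) \sim \log s]$, clipped to $[2,3]$. A
constant or planar patch yields exactly $D = 2$ because the bilinear center
lies on the plane and the triangulated area is scale-invariant; rougher
surfaces (smaller Hurst exponent) yield larger $D$.

**mBm Hurst map.** A separable, periodic 2D discrete wavelet transform
(orthonormal Daubechies filter with 4 vanishing moments, $J = 3$ levels) is
applied to the window; $V(j)$ pools the variance of all detail coefficients
at level $j$. For a 2D fractional Brownian field $V(j) \propto
2^{j(2H+2)}$, so $H = (\beta - 2)/2$ with $\beta$ the least-squares slope of
$\log_2 V(j)$ on $j$, clipped to $[0,1]$. White noise gives $\beta \approx
0$, hence the clipped estimate 0; a numerically flat patch (all detail
variances below $10^{-20}(1 + \overline{x^2})$) is flagged degenerate and
reported at the upper clip. The standalone estimator `mbm_hurst()` on
$128^2$ patches recovers generator Hurst exponents within $\pm 0.1$ and
agrees with an independent variogram-slope oracle; the map necessarily uses
much smaller ($16^2$) windows, where estimates are noisier but unbiased
enough to be informative as a field.

**Hölder exponent map.** Pointwise regularity: the oscillation
$\mathrm{osc}_r$ (max − min) of intensity within Chebyshev balls of radii
$r \in \{1,2,3,4\}$ scales as $r^{\alpha}$; $\alpha$ is the slope of
$\log(\mathrm{osc}_r + \varepsilon)$ on $\log r$ with
$\varepsilon = 10^{-6}$, capped at 2 for locally constant neighborhoods.
Analytic checks: a square-root radial cusp has $\alpha = 0.5$, a linear
ramp $\alpha = 1$.

None of the window or scale parameters is fixed by the estimators'
definitions, so all of them are exposed in `fractal_map_config()`; the
defaults above are conventional choices for 1 mm isotropic brain MRI. Maps
are computed slice-wise in 2D (axial), matching the estimators' classical
2D formulations; the Hölder oscillation alone uses true 3D balls.

## The feature catalogue

`assemble_case_features()` produces 516 named features per case:

* **Texture (246).** A 41-feature catalogue — GLCM (10), GLRLM (13),
  GLSZM (13), NGTDM (5), standard published formulas, logarithms base 2 —
  computed on the whole tumor after equal-width quantization to 32 gray
  levels, for each of T1Gd, T2, FLAIR and each characterization map
  (PTPSA, MBM, HE). Matrices are 3D with the 13 unit offsets merged
  (symmetric GLCM, 26-connected zones); out-of-mask neighbors never count.
* **Histograms (72 + 18).** Mean, variance, skewness, kurtosis (normal = 3),
  64-bin histogram energy and entropy, for each sub-region (ED, ET, NCR) on
  each raw sequence, plus the three maps on the whole tumor.
* **Volumetrics (12).** Whole-tumor volume and the ratio system over
  sub-region and brain volumes (zero denominators give 0 with a flag).
* **Shape (168).** For each region (WT, ED, ET, NCR) and each projection
  axis (x, y, z): area, bounding box, centroid, perimeter, axis lengths and
  orientation from second central moments, eccentricity, solidity, extent.

The fractal subset — exactly the features sourced from the PTPSA/MBM/HE
maps, 141 of 516 — defines the ablation: the "without fractal" variant drops
these columns and nothing else. A config switch computes the maps per
sequence (T1Gd, T2, FLAIR) instead of once from FLAIR, growing the
catalogue to 744; the published composition of "around 680" features is not
recoverable exactly from its description, so both variants are provided and
the count is validated as a range, not an equality. Missing sub-regions
contribute zeros rather than dropped columns, keeping the design matrix
rectangular across cases.

## Prediction engine

For each molecular target the labeled cases are repeatedly partitioned
(stratified 75/25 by largest-remainder allocation; 108 cases give the
classical 81/27). On each training set:

1. **Recursive feature selection.** Features are ranked by random-forest
   impurity importance (500 trees by default); for candidate sizes
   $\{2,3,5,7,9,11,13,15\}$, largest first, the surviving features are
   re-ranked and truncated, and each candidate set is scored by the AUC of
   pooled leave-one-out out-of-fold probabilities of the boosted-tree
   classifier. LOOCV folds of size one have no per-fold AUC, which is why
   the pooled form is used. The size cap of 15 keeps the training set at
   least five times the feature count. Ties in the maximal AUC resolve to
   the smallest size.
2. **Nested outer LOOCV.** Selection is re-run inside every outer fold so
   the held-out case never influences its own feature set; pooled out-of-fold
   scores give cross-validated AUC/sensitivity/specificity.
3. **Final model.** The feature set whose inner AUC is best across outer
   folds is used (ties: intersection of the tied sets; an empty
   intersection falls back to the smallest tied set, flagged), a gradient-
   boosted tree ensemble (logistic link, learning rate 0.3, depth 3, 100
   rounds, L2 weight 1, positive-class weight = class ratio; all
   config-exposed since the source methodology states none of them) is fit
   on the full training set and evaluated on the untouched test partition.

The number of repetitions is drawn uniformly from 10–15 (configurable); the
two ablation variants of one repetition share the partition, so the
with/without comparison is paired, and both the ANOVA used for the headline
comparison and a paired t-test are reported. A three-class extension
predicts IDH wild-type / IDH-mutant co-deleted / IDH-mutant non-co-deleted
jointly, scored by one-vs-rest sensitivity/specificity, overall accuracy,
and the pairwise-average multiclass AUC (Hand–Till construction).

Sensitivity and specificity use a fixed probability threshold of 0.5 with
the aberrant state (mutated / methylated / co-deleted) as the positive
class; the source methodology names no threshold or polarity, so these are
documented defaults rather than tuned values.

## The survival layer

`km_logrank_median_split()` standardizes a feature, splits at the median
(ties to the lower group), and compares the groups by Kaplan–Meier curves
with the unweighted two-group log-rank test; because the figure captions
and text of the source methodology disagree on which test produces the
quoted p-values, the likelihood-ratio p of the corresponding two-group Cox
model is always reported alongside. `cox_per_sd()` fits a univariate
proportional-hazards model on the standardized covariate, so the hazard
ratio reads as risk change per one standard deviation; confidence intervals
come from the observed information and the p-value from the likelihood
ratio. No multiple-testing correction is applied across features, matching
the source analysis; this is a documented limitation.

## What the phantom generator emulates — and what it does not

`generate_phantom_case()` builds an ellipsoidal "brain" containing nested
spherical sub-regions (necrotic core r = 4, enhancing shell r = 6, edema
shell r = 10 voxels on a 64³ grid by default), fills each modality with
region-typical mean intensities (e.g. enhancing tumor bright on T1Gd, edema
bright on FLAIR), adds fractional-Brownian texture (spectral synthesis with
amplitude $\propto (\|f\|^2 + f_0^2)^{-(2H+d)/4}$, $f_0 = 1/\text{grid}$,
unit variance, amplitude 10 intensity units) and Gaussian voxel noise
(SD 2).

The class effect is deliberately *not* a global roughness shift. A uniform
Hurst change alters second-order statistics at every lag, which ordinary
co-occurrence and run-length features detect at least as well as fractal
estimators do — under such a design the ablation contrast the package is
built to measure would not exist. Instead, driver-positive tumors receive
an *intermittent* texture: fractional fields of Hurst $H \pm
\Delta H$ (default center 0.5) blended through a smooth spatial indicator,
so local regularity varies across the tumor; driver-negative tumors receive
the amplitude-adjusted phase-randomized (IAAFT) surrogate of the same
construction, which preserves the intensity histogram and the Fourier
amplitude spectrum while erasing the spatial organization of regularity.
The two classes therefore agree in their pooled second-order and marginal
statistics and differ in exactly the property that pointwise
regularity/scaling maps estimate — mirroring the motivating biology, where
intratumoral heterogeneity rather than bulk contrast is the putative
mutation signature. With $\Delta H = 0$ the classes are statistically
identical, giving exact null cohorts for calibration tests.

Volumetric effects scale the region radii multiplicatively; survival times
are exponential with a log-linear hazard in the standardized per-case mean
in-tumor FLAIR intensity (the "driver feature"), with independent
exponential censoring. Labels for non-driver targets are independent draws,
and an exact-count mode reproduces fixed class tallies.

The phantoms are not anatomically realistic: no cortical geometry, no MR
physics, no bias fields, no multifocality, and sub-regions are concentric
spheres. Passing the pipeline's tests on phantoms therefore demonstrates
the *correctness and sensitivity of the machinery* (no leakage, calibrated
nulls, recoverable effects), not clinical performance; the published
clinical AUC levels serve only as external anchors that this codebase does
not attempt to reproduce without the original imaging data.

## Numerical choices and degenerate inputs

* Quantization is min–max equal-width, making all quantized-texture
  features invariant to affine intensity transforms of the ROI; a constant
  ROI maps to level 1 with a degeneracy flag.
* Zero-variance co-occurrence marginals set correlation and both
  information measures of correlation to 0; zero-denominator volumetric
  ratios report 0; empty regions produce all-zero shape/histogram entries —
  always flagged, never dropped, and never non-finite.
* AUC is the normalized Mann–Whitney statistic with ties counted one half;
  a brute-force pair-counting oracle in the test suite pins the two routes
  together.
* All stochastic components draw from named substreams of a single master
  seed (`withr::with_seed`, leaving the caller's RNG untouched), so a run
  configuration reproduces byte-identical cohorts, feature tables, and
  model results; manifests record the seed next to every output file.
* Orientation is reported in degrees in (−90°, 90°] from the first
  in-plane axis; perimeter is the exposed-pixel-edge count (exact for
  axis-aligned rectangles, a ~4/π overestimate for smooth disks).

## Problem sizes used in validation

The shipped tests and the acceptance script exercise the full nested
pipeline at deliberately modest sizes chosen as representative rather than
maximal: strong-effect and null cohorts of 60 and 32 phantoms on 48³ grids
(one 64³ phantom checks single-case extraction), 10 repetitions per
ablation arm, boosting reduced to 12 rounds at depth 2 and forests to 150 trees inside
the nested loops (the model defaults remain 100 rounds, depth 3, 500 trees), Cox
null calibration over 500 cohorts of n = 40, and estimator-recovery studies
over 20 seeds per condition. These sizes keep the demonstration cohorts in
the regime where the nested procedure's behavior (selection stability,
absence of optimism, null calibration) is measurable, and they are recorded
here as the package's reference validation conditions.

## Known limitations

* The characterization maps use small per-window estimators; their absolute
  Hurst/dimension values are biased at window scale even though their
  spatial statistics are highly informative. Comparisons across
  configurations should hold the window fixed.
* The 41-feature texture list and the ~680-feature total of the source
  methodology are under-specified there; the catalogue here is pinned,
  machine-readable, and config-replaceable, but not guaranteed to match the
  original composition feature-for-feature.
* Survival modeling is univariate by design (per-feature hazard ratios);
  no multivariate or time-varying extensions are provided.
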