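---
title: "Methods: PET radiomics of tumor and nodal structures, and prognostic modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics and prognostic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalPETrad)
```

# Scope and model

`nodalPETrad` implements a prognostic radiomics pipeline for
node-positive lung cancer imaged with FDG-PET. Its units of analysis are
a 3D standardized-uptake-value (SUV) image on a regular anisotropic
grid and binary regions of interest: the primary tumor and one to five
metastatic lymph nodes per patient, from which three nodal structures
are derived (the voxelwise union `LN_merged`, the largest node
`LN_volume`, the node with the highest SUV `LN_max`; selection ties
break deterministically to the first node in input order).

The statistical model downstream is a Cox proportional-hazards model of
overall survival with continuous imaging features as covariates,
L1-penalized for feature selection and refit unpenalized for reporting.
Everything upstream exists to produce and vet those covariates.

# Feature extraction

Each (image, ROI) pair yields 118 named features in six families.

**Discretization.** Texture families and the first-order histogram
features share one discretization contract: a fixed bin width *W* (0.5
SUV by default), with
`bins = ceil(SUV / W) − min(ceil(SUV / W)) + 1`, so the lowest occupied
bin is relabeled 1 and the number of grey levels is the largest label.
A consequence used as a test invariant: adding any whole multiple of
*W* to all ROI voxels leaves every texture feature unchanged. A fixed
bin width (rather than a fixed bin count) keeps the SUV contrast scale
comparable across ROIs of different dynamic range.

**Texture matrices.** Neighborhood is 26-connectivity at one voxel
distance; co-occurrences and runs are accumulated along the 13
sign-unique directions. Each directional co-occurrence matrix is
symmetrized and normalized to a probability distribution *before*
averaging (directions with no in-ROI pair are excluded; an ROI with no
neighboring pair at all is a texture-undefined error). The run-length
matrix averages raw run counts over the 13 directions; the size-zone
matrix counts 26-connected equal-level zones and is directionless.
Feature formulas then operate on the direction-averaged matrix. The
alternative convention — computing features per direction and averaging
the feature values — is deliberately not used; with per-direction
normalization the two agree closely for near-isotropic ROIs, and a
single matrix keeps the feature definitions self-contained.

**Degenerate inputs.** A single-level matrix makes correlation-type
GLCM features 0/0; they return their defined limits (correlation 0,
IMC1 0, IMC2 0). Zero-variance ROIs get skewness and kurtosis 0,
uniformity 1, entropy 0. All logarithms are base 2.

**Shape.** Volume is voxel count × voxel volume, reported in cc to
match clinical convention. Surface area uses the coarea identity — the
boundary area of a binary set equals the total variation of its
indicator — estimated as the integral of `|grad u|` where *u* is the
indicator smoothed with a Gaussian of σ = 0.75 × the largest voxel
dimension. On digital spheres this estimator is accurate to about 1%
and converges under grid refinement, whereas triangulating the *binary*
mask at iso-level 0.5 (marching cubes or tetrahedra) carries a constant
staircase bias (about +9% for a marching-cubes mesh on a radius-25
sphere, which caps sphericity near 0.92 however fine the grid). Since
sphericity, compactness and surface-to-volume ratios inherit any area
bias, the convergent estimator was preferred; the analytic sphere is
the test oracle. Diameters (3D and per-plane 2D) are the largest
pairwise distances between surface-voxel centers in mm; elongation and
flatness are `sqrt(λ2/λ1)` and `sqrt(λ3/λ1)` of the voxel-coordinate
covariance eigenvalues, defined as 1 for a single voxel.

**IVH.** The intensity-volume histogram uses ≥-thresholds. Range-based
features (V10…V90, I10…I90 and their four symmetric differences) are
relative to the ROI's `[min, max]`; absolute features are the volume
fraction and the absolute volume (cc) at SUV 1–9 in steps of 1,
covering the SUV range of locally-advanced NSCLC cohorts. The AUC is
the integral of the volume fraction over the normalized intensity
range; for a constant ROI every threshold retains the full volume and
the AUC is 1. The first-order and IVH rosters are frozen at 16 and 45
features so the taxonomy is stable and testable; they contain every
descriptor the reporting tables need (max/peak/mean SUV, volume).

**SUV peak** is the mean over the 3×3×3-voxel neighborhood of the
hottest ROI voxel (≈1.5 cc on a 4.07 × 4.07 × 3 mm grid), restricted to
the ROI; hot-voxel ties resolve to the first voxel in array order so
the feature is deterministic on anisotropic grids.

# Feature pre-selection

Radiomics pools are wide; only features that survive two agreement
screens enter the models.

**Robustness.** ICC between replicate measurements, retained only if
ICC > 0.85 in *every* context provided (test-retest AND
inter-observer). The ICC variant is two-way random effects, absolute
agreement, single measurement — ICC(2,1) — computed from the two-way
ANOVA decomposition; absolute agreement is the strictest standard
variant, appropriate when replicate segmentations should be
interchangeable, not merely correlated. Zero-variance features are
excluded (ICC undefined).

**Surrogacy.** A merged-node feature is kept only when interchangeable
with the same feature from a single representative node: ICC > 0.85
*and* the whole Bland-Altman 95% limits-of-agreement interval (mean ±
1.96 SD of percent differences, relative to the pair mean) inside
±10%. Containment of the full interval, not just the mean difference,
is the literal reading of a "±10% LoA" criterion. Two comparator
structures exist (largest, most active); `surrogateFilter()` defaults
to demanding agreement with **both**, the stricter reading, and exposes
the disjunctive variant. The pipeline's default configuration uses the
disjunctive rule ("either"), following the usual phrasing of surrogacy
against "the largest or most active node": under multi-node cohorts the
merged structure genuinely differs from any single node in volume-like
features, and the conjunctive rule can empty the nodal pool entirely,
whereas the disjunctive rule retains the small interchangeable core
(maximum SUV and SUV peak are *exactly* equal between the merged
structure and the most active node whenever nodes are spatially
separated, plus run-length descriptors). Both rules are one config
switch apart.

# Survival modeling

- **Selection:** `glmnet` LASSO-Cox on internally z-scored features;
  the penalty is the 10-fold cross-validated partial-likelihood
  deviance minimum (not the 1-SE rule — the less conservative default,
  exposed in config). Folds are stratified by event status with a
  recorded seed; event-free folds are re-drawn a bounded number of
  times. An empty selection is a legitimate result, not an error.
- **Reporting:** selected features are refit by unpenalized Cox on the
  full cohort; HRs, Wald CIs and p-values come from that refit. Nodal
  volume enters as its natural logarithm (log-linearity diagnostics
  below recommend it). AIC = 2k − 2·logPL; model comparison tables are
  always sorted ascending (lower preferred).
- **Discrimination:** Harrell's C counts usable pairs (earlier time is
  an observed event, or exactly one member of a time-tied pair is an
  event); risk ties count 0.5. The 95% CI is an asymptotic normal
  interval with the degree-2 U-statistic influence-function variance;
  tests cross-check it against the `survival` package's independent
  estimate.
- **Diagnostics:** log-linearity is tested by likelihood ratio between
  the linear and the penalized-spline univariable fit (non-linear if
  p < 0.05; if the raw feature is non-linear, positive, and its log
  passes, a log transform is recommended — the nodal-volume case).
  Proportional hazards uses scaled Schoenfeld residuals against
  log(time).
- **External validation:** the development coefficients are frozen and
  the linear predictor is evaluated on the validation cohort; only
  Harrell's C is reported there.

# The synthetic data generator

The generator defines the study conditions under which everything is
tested.

- **Grid:** 48 × 48 × 36 voxels at 4.0728 × 4.0728 × 3 mm — the
  development-cohort PET reconstruction grid.
- **Anatomy:** one tumor and 1–5 nodes per patient (node count uniform;
  the cohort is node-positive by construction) as random ellipsoids
  with semi-axis ratios ≤ 2, placed away from the boundary and from
  each other, with bounded retries before an explicit placement error.
  Mean radii of 24 mm (tumor) and 12 mm (node) put volumes on the scale
  of a locally-advanced cohort (tens to hundreds of cc of total
  disease).
- **Uptake:** blob mean SUV × a correlated multiplicative lognormal
  field (Gaussian-filtered white noise, exponentiated, mean 1,
  log-scale SD 0.35, correlation length 1.5 voxels). This keeps SUV
  strictly positive, gives tunable within-ROI heterogeneity for the
  texture families, and has exact degenerate limits (zero noise ⇒
  exactly constant blobs) used by tests. Across patients, mean uptake
  is drawn lognormally at cohort scale (tumor mean SUV ≈ 4.4 ± 2.3,
  nodal ≈ 3.5 ± 1.9) — without between-patient spread, agreement
  statistics like ICC are degenerate by construction.
- **Replicate segmentations:** test-retest and inter-observer
  delineations are emulated by random boundary editing (add outer /
  remove inner boundary voxels at rate 0.2 per round; the number of
  rounds is the magnitude knob). The magnitudes are calibration knobs,
  not estimates of any scanner's true variability. A perturbation whose
  erosion depth would empty the mask is refused.
- **Outcomes:** Weibull proportional hazards (shape 1.2, scale 24
  months — median survival around 20 months), log-hazard linear in
  z-scored ground-truth features; censoring is administrative (uniform
  cutoff) with the cutoff calibrated by root finding so the expected
  censored fraction hits the target. Default ground-truth coefficients
  place signal on tumor run-length texture, nodal volume, nodal
  grey-level non-uniformity and nodal uniformity — feature types of
  established prognostic interest.
- **Reproducibility:** one RNG stream per patient, derived from
  (master seed, patient index), so a cohort prefix is bit-identical
  regardless of how many patients are generated.

What the phantoms do **not** emulate: scanner point-spread and partial
volume effects, respiratory motion, reconstruction artifacts,
anatomically realistic node shapes or inter-feature correlation
structures of real tumors. Passing tests therefore demonstrate the
correctness and calibration of the computations, not clinical
performance on real cohorts.

# Pipeline and problem sizes

`runPipeline()` executes simulate → extract → preselect → model →
validate → report from one validated config (YAML-serializable, every
stochastic stage seeded; a missing seed fails validation before any
stage runs). Replicate segmentations for the ICC stage are produced for
a 40-patient subset by default — agreement studies are typically run on
small sub-cohorts, and the full cohort still feeds surrogacy and
modeling. Reports mirror the three standard tables of a prognostic
imaging study: the clinical univariable screen, the common-descriptor
table (max/peak/mean SUV, volumes, tumor load, with Pearson
correlations), and the three-model comparison with internal/external C
and ascending AIC. The manifest records per-file MD5 checksums; the
extract and preselect stages are byte-reproducible under a fixed
config.

The test suite exercises the default study scale: the end-to-end
acceptance run uses 262 development and 50 validation patients;
selection-recovery and AIC-ordering properties use 50 replicates at
n = 260 with 40% and 30% censoring; oracle equivalence for the texture
matrices uses 100 random masked volumes up to 6 × 6 × 6; concordance
calibration uses n = 2000.

# Known limitations

- The feature rosters are count-stable local conventions; other
  radiomics software may name or define individual features (notably
  IVH and first-order rosters) differently, so cross-software numeric
  agreement is not expected feature-by-feature.
- No image resampling/harmonization is implemented; features from
  cohorts with different voxel sizes are extracted on their native
  grids.
- Texture on the merged nodal structure treats spatially separate nodes
  as one ROI (runs and zones cannot bridge the gap, but the matrices
  are pooled); the per-node-aggregation alternative is not implemented.
- The C-index CI is asymptotic; for very small validation cohorts a
  bootstrap would be preferable.
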