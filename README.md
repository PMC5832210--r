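# nodalPETrad

FDG-PET radiomics prognostics for node-positive lung cancer: feature
extraction from the primary tumor **and** the metastatic lymph nodes,
agreement-based feature pre-selection, and LASSO-Cox survival modeling —
with a synthetic phantom and outcome generator so the entire pipeline is
testable end to end without patient data.

## The problem

In locally-advanced NSCLC most patients present with metastatic
hilar/mediastinal lymph nodes, yet prognostic imaging models are usually
built from the primary tumor alone. This package implements a pipeline
that quantifies the FDG uptake pattern of both structures and asks
whether nodal image information adds prognostic value for overall
survival:

1. **Structures.** Per patient: the primary tumor and the individual
   nodes, from which three nodal structures are derived — the union of
   all nodes (`LN_merged`), the largest node (`LN_volume`) and the most
   active node (`LN_max`).
2. **Radiomics.** 118 features per structure: 16 first-order statistics,
   13 shape descriptors, 45 intensity-volume-histogram (IVH) features
   and 44 texture features (22 GLCM, 11 GLRLM, 11 GLSZM). Texture
   matrices are built on SUV discretized with a fixed bin width,
   `I_D(x) = ceil(I(x)/0.5) − min(ceil(I/0.5)) + 1`, using
   26-connectivity: co-occurrences and runs are accumulated over the 13
   sign-unique 3D directions and the matrices averaged.
3. **Pre-selection.** Features must be robust — intraclass correlation
   ICC(2,1) > 0.85 across test-retest and inter-observer replicate
   segmentations — and merged-node features must be surrogate-compatible
   with a single representative node (ICC > 0.85 and Bland-Altman limits
   of agreement within ±10%).
4. **Models.** Three LASSO-penalized Cox models (10-fold CV, deviance
   minimum): tumor features, LN features, and their union; selected
   features are refit unpenalized, reported as HRs with CIs, and
   compared by Harrell's concordance index (with a Noether-type 95% CI)
   and AIC (lower preferred), with penalized-spline log-linearity and
   Schoenfeld proportional-hazards diagnostics.

## Worked example

```r
library(nodalPETrad)

sim <- simulatePatientImages(phantomSpec(seed = 42, nNodes = 3))
sim$image
#> SUVImage: 48 x 48 x 36 voxels @ 4.073 x 4.073 x 3 mm
#>   SUV range: [0.189, 11.3], mean 0.932

fv <- extractAll(sim$image, sim$tumor)
round(fv[c("stats_mean", "stats_maximum", "stats_suv_peak",
           "shape_volume_cc", "glcm_entropy", "glrlm_sre")], 3)
#>     stats_mean  stats_maximum stats_suv_peak shape_volume_cc
#>          4.451         11.324          9.124         229.955
#>   glcm_entropy      glrlm_sre
#>          6.498          0.844

merged <- mergeNodes(sim$nodes)
tumorLoad(maskVolume(sim$tumor), maskVolume(merged))
#> [1] 270.5
```

The tumor's mean SUV (4.45) and maximum SUV (11.3) sit on the scale of a
locally-advanced NSCLC cohort; `stats_suv_peak` is the mean over the
3×3×3-voxel neighborhood of the hottest voxel (≈1.5 cc at this grid).
`tumorLoad` is the combined tumor + nodal volume in cc.

Fitting a prognostic model on simulated survival (one informative
feature, per-SD hazard ratio 2, among noise):

```r
set.seed(1)
X  <- as.data.frame(matrix(rnorm(260 * 5), 260,
                           dimnames = list(NULL, paste0("f", 1:5))))
sv  <- simulateSurvival(X, survivalSpec(betas = c(f1 = log(2)),
                                        censoringRate = 0.4, seed = 2))
sel <- lassoCoxCV(X, sv$time, sv$event, seed = 3)
refitCox(X, sv$time, sv$event, sel$selected, modelId = "tumor")
#> ModelFit 'tumor': 1 feature(s) selected
#>  feature  coef   HR HR_lo HR_hi p_value
#>       f1 0.647 1.91  1.59   2.3 9.3e-12
#> C-index 0.619 (95% CI 0.568-0.670); AIC 1455.0
```

The LASSO keeps only the planted feature; the refit HR (1.91, CI
1.59–2.3) brackets the true value 2.

The whole study design runs as one configured pipeline,
`runPipeline(pipelineConfig(outDir = "run1", seed = 1))`: it simulates a
262-patient development and 50-patient validation cohort, extracts all
structures, pre-selects features, fits and externally validates the
three models, and writes univariable/common-descriptor/model-comparison
report tables plus a checksummed run manifest. A thin CLI wrapper lives
at `inst/cli/nodal-petrad.R`.

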