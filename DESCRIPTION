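Package: nodalPETrad
Title: FDG-PET Radiomics Prognostic Modeling of Tumors and Metastatic Lymph Nodes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end FDG-PET radiomics pipeline for node-positive lung
    cancer prognosis. Extracts a 118-feature radiomics vector (first-order
    statistics, shape, intensity-volume histogram, and GLCM/GLRLM/GLSZM
    texture families) from 3D standardized-uptake-value images and binary
    regions of interest; constructs merged, largest and most-active nodal
    structures; pre-selects features by test-retest/inter-observer
    intraclass correlation and Bland-Altman limits of agreement; and fits
    LASSO-penalized Cox proportional-hazards models evaluated by Harrell's
    concordance index and AIC. Includes a synthetic phantom and survival
    generator with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    glmnet,
    igraph,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
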