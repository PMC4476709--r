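Package: affectsig
Title: Development and Evaluation of Multivariate Brain Signatures of Affect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for developing whole-brain multivariate signatures that
    predict the intensity of affective experience from condition-level fMRI
    beta images. Implements LASSO-PCR (principal components regression with
    L1 selection and an OLS refit, back-projected to voxel weights),
    stratified subject-level splitting, leave-one-subject-out and
    within-subject cross-validation, bootstrap inference on voxel weights
    with uncorrected and FDR thresholding and cluster-extent filtering,
    pattern-expression measures (dot product, spatial correlations, ROI
    averages, peristimulus time courses, item analysis), signal-detection
    evaluation (forced-choice and bias-minimizing single-interval balanced
    accuracy with binomial, McNemar and two-proportion tests), benchmark
    grids against ROIs and network masks, subnetwork discovery by Ward
    clustering of rank-normalized trial-level region responses, virtual
    lesion analysis, and a synthetic multi-subject beta-image generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
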