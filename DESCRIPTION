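Package: defacingQC
Title: Automated Quality Assessment of Brain-MRI Defacing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decides whether a defaced brain-MRI scan still carries
    identifiable facial features. Extracts volumetric impact measures
    (impacted/removed head and brain voxels, brain-to-head ratio) and
    multi-view image-similarity features (RMSE, PSNR, SSIM, FSIM over five
    standardized surface renderings) from original/defaced NIfTI scan pairs,
    and classifies defacing success with nested stratified group k-fold
    cross-validation, permutation feature importance and Spearman-cluster
    feature selection. Ships a synthetic head-phantom generator that emulates
    defacing failure modes for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    RNifti,
    Rcpp,
    ranger,
    xgboost,
    nnet,
    glmnet,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
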