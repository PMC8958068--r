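Package: radrobust
Title: Robustness of CT Radiomic Features to Image Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how computed-tomography preprocessing choices
    (isotropic resampling voxel size, interpolation algorithm, and
    fixed-bin-width gray-level discretization) bias the estimation of
    radiomic features. Provides a reproducible synthetic cohort of
    CT-like lesion volumes, a 3D feature engine computing 105 features
    across seven classes (shape, first-order, GLCM, GLDM, GLRLM, GLSZM,
    NGTDM), and robustness statistics: two-way mixed-effects
    absolute-agreement single-rater intraclass correlation, per-subject
    coefficients of variation, and repeated-measures correlation with
    Bonferroni adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
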