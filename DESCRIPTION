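Package: kbpdose
Title: Knowledge-Based Planning Dose Prediction with an Attention-Gated 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts three-dimensional radiotherapy dose distributions for
    head-and-neck intensity-modulated plans from patient anatomy (CT plus
    binary contour masks for up to three planning target volumes and eight
    organ-at-risk/body structures), using an attention-gated 3D U-Net trained
    voxelwise with mean-squared error. Includes a synthetic phantom generator
    for end-to-end testing without clinical data, NIfTI and sparse-voxel I/O,
    the full preprocessing chain (cropping, intensity and dose normalization,
    missing-structure zero fill, 12-channel stacking, cohort splitting),
    hand-rolled network construction, He initialization, Adam training with
    early stopping, and dosimetric evaluation (per-structure mean absolute
    error, difference maps, dose-volume histograms, D99/Dmax/Dmean,
    homogeneity and conformity indices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
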