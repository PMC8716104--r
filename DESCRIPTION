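Package: facegrad
Title: Fine-Scale Spatial Tuning of fMRI Responses Along Cortical Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fine-scale spatial tuning of condition
    responses within functionally defined cortical regions of interest.
    Implements block-design general-linear-model estimation with a gamma
    haemodynamic response, localizer-based ROI definition with
    vein-voxel exclusion, pattern normalization and shared-pattern
    residualization, projection of voxel responses onto an anatomical
    axis to form one-dimensional spatial profiles, gradient correlation
    statistics with group-level inference, odd/even split-half
    reliability, and a compressive spatial summation (CSS) population
    receptive field model with wedge and ring apertures. A synthetic-data
    module plants known gradients, vein voxels, and receptive fields so
    that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
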