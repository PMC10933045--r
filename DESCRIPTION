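Package: voxdose
Title: Voxel-Based Modeling of Radiotherapy Dose and Nutritional Toxicity
Version: 0.1.0
Authors@R: person("voxdose", "developers", role = c("aut", "cre"),
    email = "voxdose@example.org")
Description: Tools for voxel-based analysis of radiotherapy dose and a
    composite nutritional-supplementation endpoint (feeding-tube use or
    greater than ten percent weight loss) in head and neck cancer.
    Provides a synthetic cohort generator with a planted radiosensitive
    organ subregion, contour-driven deformable registration of organ
    masks to a reference frame with dose warping and Dice quality
    control, dose-volume histogram metrics, ridge logistic regression of
    per-voxel and aggregated regional dose features with cross-validated
    penalty tuning, permutation feature importance, and an end-to-end
    reproducible pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
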