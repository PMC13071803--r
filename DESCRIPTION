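Package: radiopose
Title: Resolution Effects in Model-Based 2D-3D Bone Pose Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained framework for studying how x-ray image
    resolution affects model-based 2D-3D rigid bone pose estimation from
    biplanar radiographs. Generates synthetic bone volumes, calibrated
    biplanar camera rigs, gold-standard pose trajectories and noisy
    radiographs; renders digitally reconstructed radiographs (DRRs) by
    trilinear ray marching; refines perturbed 6-DOF poses with particle
    swarm optimisation of a normalised cross-correlation cost on
    edge-preprocessed images; quantifies pose error with helical (screw)
    axis parameters; and summarises errors with robust descriptive
    statistics (median, limits of agreement, MAD, Hampel outliers) and
    nonparametric tests (Kruskal-Wallis, Dunn with Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
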