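Package: sama3d
Title: Automated 3D Morphometry of Epithelial Structures in Confocal
    Z-Stacks
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs, measures and statistically compares populations
    of three-dimensional epithelial structures (acini and ducts) imaged as
    confocal z-stacks of 3D cultures.  Provides tiered preprocessing
    (local background removal, 3D rank filtering, Gaussian smoothing,
    depth-luminosity compensation, gradient-based separation of touching
    structures), threshold segmentation with 26-connected labeling,
    per-structure shape descriptors (elongation, flatness, sphericity,
    ratio volume ellipsoid), lumen (cavity) detection with relative lumen
    volume, skeleton-based branching complexity, and a statistics layer
    that compares conditions with the larger of ANOVA and exact Wilcoxon
    p-values, principal component overviews and replicate reproducibility
    curves.  A seeded ellipsoid phantom generator with voxel-level ground
    truth allows the whole pipeline to be validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
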