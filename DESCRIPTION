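Package: tfm3d
Title: Three-Dimensional Traction Force Microscopy by Digital Volume Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward three-dimensional traction force microscopy for cells on
    compliant hydrogels. Recovers full-field 3D displacements from pairs of
    volumetric bead images by FFT cross-correlation of cubic subsets with
    3D quadratic subvoxel peak localization, converts displacements to strain
    by pointwise least-squares displacement gradients, applies an
    incompressible linear-elastic constitutive law, and evaluates Cauchy
    traction vectors on arbitrary planes. Includes a synthetic confocal
    z-stack generator with analytic deformation maps for ground-truth
    validation, material calibration from compression records, zero-load
    sensitivity analysis, and control-volume force/moment balance checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    Rcpp,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
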