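Package: morphopipe
Title: Restartable Registration Pipelines and Deformation-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for building and executing image
    registration pipelines on 3-D volumes. Provides a dependency-inferring,
    checkpointable pipeline engine with duplicate-stage elimination and
    resource-aware scheduling; native registration atoms (Gaussian blur
    pyramids, rigid/affine simplex registration, demons-style nonlinear
    registration, resampling, averaging, label voting); a transform algebra
    (affines, dense displacement fields, chains, inversion, Jacobian
    determinants); transform-tracking file handlers; four complete
    applications (iterative group-wise model building, longitudinal
    registration chains, two-level registration, multi-atlas label fusion);
    deformation-based-morphometry statistics; and a labeled-phantom
    generator so every pipeline is testable from synthetic data alone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    digest,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
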