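Package: microdyn
Title: Microglial Population Dynamics Across the Human Cortical Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative histology and trajectory statistics for microglial
    population dynamics in the developing human cortex. Provides density,
    proliferative (IBA1/Ki67) and apoptotic (IBA1/cleaved caspase-3) index
    quantification on layered cortical columns, morphometric classification of
    migratory phenotypes (circularity and major-axis orientation), kernel
    density heatmaps of cell counts with fixed sampling radius, excess-mass
    multimodality ("wave") testing with critical-bandwidth bootstrap
    calibration, temporal-window assignment and nonparametric comparisons,
    Loess-plus-spline trend fitting, and TPM-threshold constitutive-expression
    classification with single-cell MAD quality filtering. A synthetic-data
    module generates cortical-column point patterns, lifespan cohorts with
    planted proliferation/density waves, and expression matrices with known
    gene classes, providing ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Matrix,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
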