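Package: ecosuit
Title: Presence-Only Maximum-Entropy Habitat Suitability and Land-Cover
    Change Analysis
Version: 0.1.0
Authors@R:
    person("CERNAS", "Spatial Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for presence-only species distribution modelling and
    multitemporal land-use/land-cover (LULC) change analysis on regular
    raster grids.  Implements a maximum-entropy (MaxEnt-style) model from
    first principles: feature expansion (linear, quadratic, product, hinge,
    threshold, categorical), L1-regularized fitting by cyclic coordinate
    descent, raw/logistic/cloglog outputs, training gain, AUC, percent
    contribution, permutation importance and jackknife variable analysis.
    Includes raster grid utilities (plain-text ASCII grid I/O, resampling,
    Horn slope/aspect), occurrence thinning to one record per grid cell,
    convex-hull occurrence areas, Pearson-correlation collinearity pruning,
    suitability thresholding and equal-interval classification,
    present-vs-future presence change, class-area tables and
    transition matrices for categorical LULC epoch series, seeded synthetic
    data generators, and a configuration-driven pipeline with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
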