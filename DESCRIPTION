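Package: canopyrich
Title: Height-Structured Habitat Metrics and Avian Richness Models from
    Canopy Height Rasters
Version: 0.1.0
Authors@R: person("Q.", "Analyst", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes four sets of landscape habitat metrics from gridded
    canopy-height rasters (summary height statistics; traditional
    patch-based metrics on the binary vegetation map; height-structured
    patch and depth-weighted edge metrics on a height-segmented map; and
    grey-level co-occurrence texture metrics), estimates
    detection-adjusted avian species richness per survey route with the
    first-order jackknife, and compares linear and random-forest richness
    models with bias-corrected and accelerated (BCa) bootstrap confidence
    intervals and out-of-bag permutation importance. Includes a synthetic
    landscape and survey generator so that the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
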