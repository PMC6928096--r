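Package: turpeval
Title: Synthetic Prostate-Phantom Imaging and Quantitative Evaluation of
    Transurethral Resection Performance
Version: 0.1.0
Authors@R:
    person("Phantom", "Metrics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to generate synthetic two-zone prostate-phantom
    ultrasound slice stacks with ground-truth labels, simulate
    skill-parameterized transurethral resections, automatically segment
    the resulting B-mode-like images, and score surgical performance with
    three shape statistics: preservation of the peripheral zone (ratio of
    minimum wall thickness before and after resection), smoothness of the
    resection boundary (cavity solidity), and circularity of the
    resection area. Includes percentage score cards with radar-chart
    export, two-sample t-test group comparisons, and a flat-punch
    indentation module that computes the compressive elastic modulus of
    phantom materials from cyclic force-displacement traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
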