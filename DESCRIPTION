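Package: wormforage
Title: Stochastic Simulation and Changepoint Analysis of C. elegans
    Foraging Reorientations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of Caenorhabditis
    elegans reorientation events during off-food foraging, driven by a
    decaying signalling factor M that couples multiplicatively to the
    reorientation propensity.  Includes rolling-window rate curves,
    nonlinear least-squares fitting of the three-parameter exponential
    rate decay, two-segment linear-regression changepoint analysis of
    cumulative reorientation curves, Jensen-Shannon divergence
    comparison of (slope difference, transition time) distributions
    across model variants with Tukey HSD, surrogate-data generators,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
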