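Package: phylovalid
Title: Validation Protocols for Bayesian Phylogenetic Model Implementations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for checking that a Bayesian evolutionary model is correctly
    implemented, both as a simulator and as an inference engine. Provides direct
    simulators for Yule (pure-birth) trees, Kingman coalescent trees and
    phylogenetic Brownian motion traits; exact log-densities for every model
    component and a small Metropolis-Hastings sampler with scalar and time-tree
    proposals; coverage validation of highest-posterior-density intervals against
    binomial acceptance bounds; rank-uniformity validation (simulation-based
    calibration) with histogram and ECDF band diagnostics; and two tree-space
    procedures: rank-uniformity of tree-to-reference distances (Robinson-Foulds
    by default) and clade-support coverage calibration. Scenario presets
    orchestrate the full simulate-infer-calibrate pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
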