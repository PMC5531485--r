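Package: hexpassage
Title: Stochastic Lattice Simulation of Cell Culture Passaging and Scratch Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Agent-based simulation of two-dimensional cell culture on a
    hexagonal lattice with volume exclusion. Individual cells move and
    proliferate with per-time-step probabilities; each cell carries a
    heritable proliferation probability drawn from a normal distribution, so
    populations can be near-homogeneous or heterogeneous. The package
    implements the serial passaging protocol (seed at 15% confluence, grow to
    85%, split, apply stochastic damage to the proliferation probability) and
    an in silico scratch (wound-healing) assay with ensemble-averaged column
    density profiles, allowing the trade-off between initial heterogeneity
    and passage-induced damage, and its consequences for scratch-closure
    dynamics, to be explored quantitatively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
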