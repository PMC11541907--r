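Package: decaylab
Title: Massively Parallel mRNA Decay Analysis for Barcoded Reporter Libraries
Version: 0.1.0
Authors@R:
    person("decaylab", "maintainers", email = "decaylab@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of massively parallel rifampicin-chase
    measurements of bacterial mRNA decay. Generates barcoded 5' UTR design
    libraries with ground-truth first-order decay constants, simulates
    multinomial sequencing counts with a fixed-mass RNA spike-in, maps reads
    to barcodes with single-mismatch tolerance, estimates per-variant decay
    constants and half-lives by exponential fitting of spike-in-normalized
    ratios, computes isoform-aware biophysical features (transcription and
    translation initiation surrogates, secondary-structure anatomy,
    G-quadruplex and i-motif detection, motif counts), trains staged
    gradient-boosted tree models of mRNA levels and decay rates, and extracts
    design rules by systematic model queries and multi-factor stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
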