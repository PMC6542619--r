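Package: coreplex
Title: Core-Periphery Analysis of Multiplex Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the core-periphery analysis of multiplex (multilayer)
    brain networks built from heterogeneous connectivity modalities such as
    DWI tractography, resting-state fMRI and band-specific MEG coherence.
    Computes per-node coreness over a density-threshold sweep of the weighted
    multiplex, optimizes the layer contribution coefficients on the positive
    unit hypersphere by particle swarm maximization of a Fisher separation
    criterion between two groups, quantifies core-periphery reorganization
    with the coreness disruption index and its behavioral correlates, and
    simulates core- or periphery-targeted disconnection processes. Includes a
    seeded synthetic cohort generator with planted core structure and
    band-averaged spectral coherence estimation from multichannel epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
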