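Package: chromfold
Title: Multiscale Bead-Chain Reconstruction of 3D Chromatin from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates populations of plausible three-dimensional chromatin
    configurations from Hi-C contact matrices, optionally complemented by
    CTCF loop-anchor pairs (ChIA-PET), H3K27me3 intervals and expressed-gene
    intervals. The chromatin fibre is modelled as a chain of modified beads
    (centroid, two endpoints, approximate radius); TAD-like diagonal blocks
    of the contact matrix are reconstructed independently by approximated
    simulated annealing with quaternion pivot and crankshaft moves, then
    summarised as single beads at the next coarser scale, recursively, and
    finally re-expanded top-down to the input resolution. Reconstructed
    ensembles are validated by re-simulating contact matrices and comparing
    them with the input by Spearman correlation, including a resampling
    stability analysis and a missing-data/CTCF-rescue protocol. A synthetic
    toy-chromatin generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
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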