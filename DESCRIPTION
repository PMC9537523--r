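Package: organoidkit
Title: Intrinsic Electrophysiology, Multi-Electrode Array, and Single-Cell
    Transcriptomic Analysis for Telencephalic Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and phenotype clustering for current-clamp
    recordings of organoid neurons (rheobase, dV/dt spike threshold, spike
    shape, adaptation index, F-I slope, passive membrane properties, sag
    ratio; missing-aware correlation-distance average-linkage clustering),
    thresholded event-rate and spectrogram analysis of extracellular
    multi-electrode array recordings, and single-cell RNA-seq quality
    control, highly-variable-gene selection with two-step cell-cycle gene
    removal, marker ranking, and Jaccard marker-set similarity. Every
    analysis stage ships with a seeded synthetic-data generator (adaptive
    leaky integrate-and-fire neurons, Poisson spike trains on colored noise,
    negative-binomial UMI counts) providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    signal,
    minpack.lm,
    Matrix,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
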