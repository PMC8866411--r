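Package: newtblur
Title: Newtonian Blurring Augmentation for Repeated-Tractography Braingraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data augmentation for ensembles of repeatedly reconstructed,
    fiber-count-weighted braingraphs. Probabilistic tractography yields a
    slightly different connectome on every run; Newtonian blurring turns the
    R repeated runs of one subject into all choose(R, k) subset graphs, each
    obtained by deleting edges that vanish in any chosen run and assigning
    every surviving edge the min/max-trimmed mean of its k subset weights.
    The package provides the core blurring and basic-averaging algorithms,
    edge-set Jaccard-distance diagnostics with within/between-subject pair
    analyses, a reproducible synthetic cohort generator emulating repeated
    tractography, a linear support-vector-machine augmentation experiment
    with penalty rescaling (C divided by the augmentation fold), and CSV /
    GraphML readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
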