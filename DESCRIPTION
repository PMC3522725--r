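Package: mtquant
Title: Quantification of the Cellular Microtubule Pool from Fluorescence
    Images, Densitometry and Plate-Reader Data
Version: 0.1.0
Authors@R: person("mtquant", "maintainers", email = "mtquant@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the polymerized microtubule pool in cultured
    cells: integrated-density (AID) immunofluorescence measurements with
    histogram-derived positive cutoffs, tyrosinated/detyrosinated
    (Tyr-MT/Glu-MT) ratio analysis with below-detection handling,
    focal-plane selection on z-stacks, microtubule network area measurement,
    in-cell-western per-well normalization to a nuclear stain, polymerized
    versus soluble fraction densitometry for tubulin and tau, growth-cone
    peripheral-domain invasion scoring, viability normalization, and a group
    statistics layer (one-way ANOVA, Dunnett many-to-one and
    Student-Newman-Keuls post-hoc tests, dose-response shape classification).
    A synthetic-data generator with recorded ground truth emulates every
    input type so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mvtnorm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
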