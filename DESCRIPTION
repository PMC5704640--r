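Package: reosig
Title: Rank-Based Gene-Pair Signatures Robust to Low-Input RNA Amplification Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the robustness of within-sample relative
    expression orderings (REOs) of gene pairs against the distortion
    introduced by low-input RNA amplification. Quantifies amplification
    bias through fold changes between paired low- and high-input
    profiles, detects stable gene pairs and scores REO consistency
    between profiles, discovers reversal gene-pair signatures between
    two tissue classes with majority-vote classification, aggregates
    single cells into pseudo-bulk samples, and simulates all required
    inputs (dilution ladders, two-class cohorts, high-dropout single
    cells) so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
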