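Package: scarray
Title: Concordance Analysis of Single-Cell Two-Color Microarray Profiles
Version: 0.1.0
Authors@R: person("Array", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing whether two-color microarray profiles
    amplified from one, five, or ten cells recapitulate pooled-cell
    profiles. Implements sample quality control with Dixon's Q test,
    a normalization chain (experimental-day correction, normal-exponential
    background correction, within-array loess, between-array quantile
    normalization), fixed-threshold detection calling, sensitivity and
    specificity with Beta posterior credible intervals, M-ratio concordance
    statistics including a seeded random-pair difference correlation,
    gene set enrichment analysis with permutation-based NES and FDR,
    hierarchical clustering of the most variable genes, an RT-qPCR
    delta-Cq validation arm, and a seeded synthetic-data generator that
    emulates transcript capture dropout in low-input amplification
    experiments so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
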