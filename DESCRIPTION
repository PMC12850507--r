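Package: tribechip
Title: HyperTRIBE Edit-Site Calling and Clonal Hematopoiesis Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for mapping RNA-binding-protein targets with
    ADAR-fusion (HyperTRIBE) editing data and for modeling clonal
    hematopoiesis dynamics. Calls A-to-G RNA edit sites from per-sample
    allele-count tables with a negative-binomial generalized linear model
    (log link, coverage offset), estimates per-group editing frequencies by
    no-intercept regression, applies Benjamini-Hochberg correction and
    threshold-based retention, and summarizes targets with per-gene
    HyperTRIBE scores. Integrates scores with rank-sum differential
    expression to define a threshold-based regulatory network, scores
    3'UTR k-mer motif enrichment around edit sites against length-matched
    background segments, classifies serial-sample CHIP mutations as
    persistent or transient, fits compound-interest clonal growth-rate and
    transience regressions, quantifies allele-specific read skew, and pools
    per-cohort effects by inverse-variance fixed-effect meta-analysis. A
    seeded synthetic-data generator with ground-truth tables makes every
    stage testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
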