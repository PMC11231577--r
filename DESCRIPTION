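Package: zincatac
Title: Chromatin Accessibility and Motif Enrichment Analysis Under Zinc
    Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how perturbations of the labile
    nuclear zinc pool reshape chromatin accessibility. Provides FRET-sensor
    calibration of nuclear Zn2+ concentrations via the Hill equation,
    genomic interval algebra (merge, blacklist subtraction, fraction-overlap
    intersection, promoter/genic/nongenic annotation), FIMO-style position
    weight matrix scanning with exact dynamic-programming p-values, a
    simplified negative-binomial Wald test for differential accessibility,
    rank-based transcription factor motif enrichment (E-scores) with
    permutation significance, ChIP-qPCR percent-input quantification with
    standard curves, candidate binding-site selection, and a seeded
    synthetic-data generator that emulates every input so the full pipeline
    is testable without external sequencing or imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
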