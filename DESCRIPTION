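Package: stemloopr
Title: Stem-Loop RT-qPCR Assay Design and Analysis for Conserved microRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying and quantifying highly conserved microRNAs
    in non-model organisms by stem-loop reverse-transcription PCR. Builds
    stem-loop RT primer / forward primer / universal reverse primer sets from
    mature miRNA sequences, simulates the reverse-transcription and PCR steps
    to predict amplicons and classify sequenced clone reads, screens genomic
    or EST sequence for hairpin precursor candidates containing a mature
    miRNA, and analyses qPCR output (dilution-series amplification
    efficiency, 2^-ddCt relative quantification against a reference gene and
    calibrator stage, and Duncan multiple-range letter grouping). Includes
    seeded synthetic-data generators for every input class so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
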