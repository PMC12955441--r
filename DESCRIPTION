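Package: cifquant
Title: Absolute Quantification of Rare Transcripts by Duplex RT-ddPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for duplex reverse-transcription droplet
    digital PCR (RT-ddPCR) assays that count rare Wolbachia cifA and cifB
    transcripts against a spike-in RNA or an endogenous reference gene.
    Provides per-droplet two-channel threshold fitting and classification
    with crosstalk compensation and amplitude-competition handling, Poisson
    absolute quantification with confidence intervals, limit-of-detection
    estimation from no-template controls, spike-in and reference-gene
    normalization, dilution-series accuracy and precision statistics, a
    droplet-level simulator with known ground truth, and assay-design QC
    (nearest-neighbor melting temperatures, oligo design rules, in-silico
    PCR, and a codon-aware alignment gap filter).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    dplyr,
    ggplot2
Config/testthat/edition: 3
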