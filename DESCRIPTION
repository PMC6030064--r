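Package: chromstates
Title: Bivalent Promoter States, Chromatin-State Transitions, and
    Regulatory Dynamics from ChIP/ATAC Fragment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a desk-scale pipeline around bivalent chromatin
    in embryonic stem cells: Poisson ChIP-versus-input enrichment
    testing with Benjamini-Hochberg correction, windowed
    enriched/depleted region calling, four-state promoter
    classification from H3K4me3/H3K27me3 marks with wild-type to
    knockout transition and retention analysis, transcription-factor
    binding-fate (loss versus replacement) classification from peak
    sets, ATAC-seq nucleosome-free fragment filtering and in-peak
    accessibility comparison, time-course transcriptional-module
    clustering, and AP-MS unique-peptide interactome filtering.
    Includes seeded synthetic-data generators with planted ground truth
    for every stage, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
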