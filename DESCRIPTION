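Package: litmeth
Title: LTR-Initiated Transcription Units and the Oocyte Methylome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of LTR-initiated transcription units (LITs)
    and DNA methylation in mammalian oocytes. Provides methylome segmentation
    by exact penalized changepoint detection, binned methylation scoring with
    CpG coverage filters, LIONS-style classification of assembled transcripts
    by their 5' relationship to LTR retrotransposons, cross-species syntenic
    mapping through UCSC chain files (liftover, reciprocal-best bins, CpG
    island identity), attribution of hypermethylated domains to transcription
    units, classification of methylated CpG islands by LIT embedding, strain
    differential calling, and post-fertilization persistence classification.
    Includes a synthetic multi-species cohort generator with a ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
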