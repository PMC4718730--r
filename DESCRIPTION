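Package: hcrtseq
Title: Cell-Type-Specific Transcript Enrichment, Promoter Motif Analysis and
    Zebrafish Sleep Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying transcripts enriched in
    FACS-sorted neuron populations from bulk RNA-seq count data, predicting
    shared transcription-factor regulators of the enriched set from conserved
    promoter binding sites, and scoring sleep architecture of zebrafish larvae
    from minute-binned locomotor activity traces. Includes calibrated synthetic
    data generators (overdispersed count matrices with planted cell-type-specific
    genes, promoter sets with planted conserved motif instances, and two-state
    activity traces with genotype-dependent night sleep) so that every stage of
    the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
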