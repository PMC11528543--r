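Package: nomepipe
Title: Single-Base NOMe-seq Methylation, Accessibility and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of nucleosome occupancy and methylome
    sequencing (NOMe-seq) together with companion RNA-seq procedures.
    Separates endogenous CpG methylation (WCG trinucleotide context) from
    exogenous GpC methyltransferase footprints of chromatin accessibility
    (GCH context) at single-base resolution, calls differentially methylated
    regions by sliding-window t-tests with Benjamini-Hochberg control, calls
    nucleosome-depleted regions by a chi-squared test against the genomic
    background with proximal/distal classification, and implements the
    expression-side procedures: RPKM quantification, differential-expression
    gating, lncRNA to protein-coding cis-pair annotation, isoform ratios,
    fetal-gene-program construction and drug-reversal quantification. Ships
    a fully seeded synthetic-data generator with truth tables for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
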