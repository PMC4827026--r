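Package: histcoloc
Title: Histone Modification ChIP-Seq Signal, Co-Localization and Peptide
    Mass Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing where a histone modification sits on
    the genome and how it relates to gene expression. Implements
    input-normalized ChIP-seq signal intensity (binned RPKM difference),
    expression-decile stratification of genes, TSS-anchored and
    gene-body-rescaled aggregation profiles of peak calls or raw signal,
    region-level fold change, a Jaccard-curve similarity statistic for
    thresholded genomic tracks, transcription-factor motif co-localization
    profiling, and monoisotopic mass computation for modified histone
    peptides. A seeded synthetic-data generator produces annotation,
    expression and read files with planted enrichment so the whole pipeline
    is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
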