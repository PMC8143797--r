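Package: fusionomics
Title: Integrative Multi-Omic Set Analysis for Chimeric Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how chimeric transcription factors reshape a
    transcriptional program across RNA-seq, ChIP-seq, ATAC-seq, proximity
    labeling (BioID) and RNAi screen readouts. Implements hypergeometric
    gene-set overlap statistics on the negative log10 density (HGD) scale,
    strand-aware peak-to-TSS annotation with distance categories and binned
    TSS occupancy profiles, position-weight-matrix scanning with exact
    dynamic-programming score p-values, consensus accessible-chromatin peak
    sets and baseline/unique gene-set partitions, SAINT-style prey filtering
    with a multi-step interactome prioritization cascade, and growth-curve
    based shRNA screen ranking. A seeded synthetic-data generator emulates
    the statistical structure of each input so the whole pipeline runs and is
    tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
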