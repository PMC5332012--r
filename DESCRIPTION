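Package: bartrap
Title: Deconvolution of Barcoded Transposon Drug-Sensitivity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for pooled insertional-mutagenesis screens in
    which each piggyBac gene-trap transposon carries a random 25-bp barcode
    at both ends. Counts barcodes from amplicon sequencing reads and clusters
    near-identical barcodes arising from PCR or sequencing error, links
    barcodes to genomic integration sites from paired inverse-PCR reads,
    filters and merges sites, annotates them with gene models, tests each
    barcode for drug-induced depletion or enrichment with a negative-binomial
    exact test after trimmed-mean-of-M-values normalization, and aggregates
    evidence across independent insertions in the same gene. A screen
    simulator generates complete synthetic inputs (genome, gene models,
    mutant libraries, selection, FASTQ reads) with a machine-readable truth
    table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    igraph,
    optparse
Config/testthat/edition: 3
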