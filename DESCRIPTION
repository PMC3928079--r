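Package: capra
Title: Chromatin Architectural Protein Occupancy, Ratio and Nucleosome
    Spacing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of chromatin architectural proteins
    (linker histone H1 and the high mobility group protein HMGD1) from
    MNase-based nucleosome ChIP-seq data. Infers nucleosome midpoints from
    single-end reads (strand cross-covariation offset) and paired-end
    reads (fragment-size filtered pair midpoints), computes occupancy
    densities over genomic features and around transcription start sites,
    relates the HMGD1/H1 log-ratio to gene expression and DNase I
    hypersensitive site distance via Pearson correlations and nested
    linear-model F-tests, clusters occupancy with histone
    post-translational modification tracks using a 1-R distance, and
    estimates local nucleosome repeat lengths from phasograms stratified
    by occupancy-ratio quintile. Ships a ground-truthed synthetic-data
    generator so every pipeline stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
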