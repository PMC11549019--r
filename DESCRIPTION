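Package: atacqc
Title: Single-Pass Quality Control and Read Filtering for ATAC-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simultaneous quality control and read filtering of coordinate-sorted
    ATAC-seq BAM files in a single pass. Computes read-category counts for
    nuclear, mitochondrial and plastid sequences, fragment-length, alignment
    length, MAPQ, GC and genome-wide depth distributions, fraction of reads in
    peaks (FRiP), TSS enrichment scores and pileups, Tn5 insertion footprint
    profiles, fragment-length periodicity, and filter parameter grid searches.
    Optionally writes a filtered BAM and machine-readable JSON reports, and
    ships a synthetic paired-end fixture generator with exact truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
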