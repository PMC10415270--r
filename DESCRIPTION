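Package: nanomethqc
Title: Quality Control and Technical Validation of Nanopore 5mC Methylation
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the technical validation of whole-genome 5mC
    methylation profiling from Oxford Nanopore long reads: read filtering
    and accuracy statistics from CIGAR and Phred qualities, decoding of
    MM/ML base-modification tags, strand-aware CpG pileups and collapsing,
    regional (100 kb bin and promoter) methylation, subsampling saturation
    curves, GC-bias coverage profiles, cross-dataset correlation, and
    chain-file liftover of per-site methylation between assemblies. A
    synthetic-data generator produces a toy genome with a known
    ground-truth methylome, ONT-like modified-base alignments, WGBS-like
    GC-biased site tables, and chain files so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
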