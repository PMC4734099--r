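Package: srnaflow
Title: Prediction of Conserved Small RNAs from dRNA-Seq TSS Maps and
    Intrinsic Terminators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genome-wide pipeline for nominating candidate bacterial small
    regulatory RNAs (sRNAs) by combining experimentally mapped transcription
    start sites (dRNA-Seq), Rho-independent transcriptional terminators and
    cross-genome conservation profiling, as applied to heterocystous
    cyanobacteria. Intergenic (orphan) TSSs are paired with downstream
    intrinsic terminators under a transcript size window, near-identical
    copies are collapsed into sequence families with one representative per
    family, candidates are profiled against a panel of related genomes with a
    query-coverage positive-hit rule, clade-exclusive candidates are flagged,
    and conserved small open reading frames inside homolog alignments are
    scored with a permutation test for synonymous-position substitution bias.
    A fully specified synthetic-data generator with known ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
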