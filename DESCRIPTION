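Package: nanojoint
Title: Joint Single-Molecule Calling of CpG and Adenine Methylation from
    Nanopore Signal Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Calls endogenous CpG methylation (5mC) and exogenous adenine
    methylation (6mA) jointly on individual nanopore reads from
    event-aligned current signal. Implements an expanded six-letter
    nucleotide alphabet with k-bar equivalence classes for partially
    methylated adenines, Gaussian-emission hidden Markov models over
    match/skip/bad/softclip state blocks, per-read shift/scale/variance
    normalisation, expectation-maximisation training of per-k-mer mixture
    emission models with a fixed initialisation grid and consistency-based
    parameter assignment, log-likelihood-ratio classification of CpG
    substrings and 50-bp adenine windows under four modification
    hypotheses, IgG background correction, and haplotype-resolved
    allele-specific statistics (Fisher exact tests and window bootstrap
    with Benjamini-Hochberg correction). A seeded simulator generates
    event-aligned reads with known methylation truth so the whole pipeline
    is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
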