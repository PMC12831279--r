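Package: buildaudit
Title: Audit Genome Assemblies and Annotations Against a Curated Transcript Library
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies per-gene assembly and annotation errors of a genome build
    against a trusted transcript/protein library, the way manual genome audits are
    carried out: spliced transcript-to-genome mapping, selenocysteine-aware
    translation with a protein-length checksum, a five-way error taxonomy
    (error in locus, split loci, merged loci, not annotated, sequence absent),
    genome-wide indel-rate estimation with exact Poisson intervals, tiered
    three-species orthology (protein, RNA, synteny) with Venn asymmetry
    statistics, protein domain-architecture comparison, readthrough-gene
    confidence scoring, and hypergeometric over-representation tests. Ships a
    synthetic-genome simulator that injects each documented error class with a
    machine-readable truth ledger, so every classifier can be benchmarked by
    injection and recovery.
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
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    methods,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
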