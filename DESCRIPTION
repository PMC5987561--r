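Package: damidstates
Title: DamID-Seq Binding-State Analysis at GATC-Fragment Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of DamID-seq chromatin profiling experiments at
    the resolution of individual GATC restriction fragments. Builds the GATC
    fragment index from a genome sequence, assigns reads to fragments under
    strict containment, constructs Dam-normalised log2 binding profiles with
    replicate-discordance masking, and segments profiles into depleted,
    intermediate and enriched binding states with a three-state heterogeneous
    hidden Markov model whose transition probabilities relax with the physical
    distance between adjacent fragments. Binding-state calls from two
    conditions are compared fragment-by-fragment into gain/loss/no-change
    transition maps, integrated with differential expression over TSS
    regulatory windows into target-gene groups, and quality-controlled with
    profile correlations, hierarchical clustering, lag autocorrelation and
    state-specific fragment-size summaries. A fully seeded synthetic-data
    generator emulates the statistical structure of DamID-seq data so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
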