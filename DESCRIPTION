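Package: zeitbind
Title: Diurnal Transcription-Factor ChIP-Seq Phase-Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for diurnal
    transcription-factor ChIP-seq experiments sampled at several zeitgeber
    times across multiple genotypes (inbred parents and their reciprocal F1
    hybrids). Provides fragment deduplication and down-sampling depth
    normalization, a Poisson local-background peak caller with replicate
    concordance and per-genotype master-peak lists, 10-kb target-gene
    assignment with genomic-feature classification, ANOVA-based binding-phase
    assignment with Fisher's exact temporal-shift and target-overlap tests,
    consensus-motif scanning with dinucleotide-shuffle enrichment,
    hypergeometric GO enrichment with Benjamini-Hochberg correction,
    mid-parent-value heterosis statistics for qPCR expression series, and
    FFT-seeded nonlinear least-squares estimation of circadian period and
    relative amplitude error. A seeded synthetic-data generator with planted
    ground truth (binding phases, motifs, GO labels, expression modes) makes
    every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
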