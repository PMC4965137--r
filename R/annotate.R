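#' Assign peaks to target genes within a distance window
#'
#' A gene is a target of a peak when the peak overlaps the gene span
#' extended by `window` bp on both sides (default 10 kb). A peak lying
#' within the window of several genes is assigned to all of them. With
#' `mode = "tss"` the window is centered on the TSS instead of the gene
#' span.
#'
#' @param peaks A `peak_set` (any source level; master peaks typical).
#' @param genes Gene-model data.frame as produced by [simulate_genome()]
#'   (needs `gene_id`, `start`, `end`, `tss`).
#' @param window Assignment distance in bp.
#' @param mode `"span"` (distance from the gene span, default) or `"tss"`.
#' @return data.frame with one row per (gene, peak) assignment: `gene_id`,
#'   `peak` (row index into `peaks`), `genotype`, `zt`.
#' @examples
#' sim <- simulate_genome(sim_design(n_genes = 3, seed = 2))
#' pk <- data.frame(chrom = "chr1", start = sim$genes$tss[1] - 500,
#'                  end = sim$genes$tss[1] - 100)
#' assign_targets(pk, sim$genes)$gene_id
#' @export
assign_targets <- function(peaks, genes, window = 10000L,
                           mode = c("span", "tss")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0 || nrow(genes) == 0) {
    return(data.frame(gene_id = character(), peak = integer(),
                      genotype = character(), zt = character(),
                      stringsAsFactors = FALSE))
  }
  if (mode == "span") {
    lo <- genes$start - window
    hi <- genes$end + window
  } else {
    lo <- genes$tss - window
    hi <- genes$tss + 1L + window
  }
  gene_ir <- IRanges::IRanges(lo + 1L, hi)  # half-open -> 1-based closed
  peak_ir <- IRanges::IRanges(peaks$start + 1L, peaks$end)
  hits <- IRanges::findOverlaps(peak_ir, gene_ir)
  q <- S4Vectors::queryHits(hits)
  out <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    peak = q,
    genotype = if ("genotype" %in% names(peaks))
      peaks$genotype[q] else NA_character_,
    zt = if ("zt" %in% names(peaks)) peaks$zt[q] else NA_character_,
    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$peak), , drop = FALSE]
}

# feature intervals per category, with the classification precedence applied
# so the categories partition the genome
feature_partition <- function(genes, genome_length, promoter_width = 2000L,
                              downstream_width = 2000L) {
  ir <- function(start, end) {
    keep <- end > start
    IRanges::reduce(IRanges::IRanges(start[keep] + 1L, end[keep]))
  }
  prom <- promoter_interval(genes$tss, genes$strand, promoter_width,
                            genome_length)
  down_start <- ifelse(genes$strand == "+", genes$end,
                       pmax(0L, genes$start - downstream_width))
  down_end <- ifelse(genes$strand == "+",
                     pmin(genome_length, genes$end + downstream_width),
                     genes$start)
  cats <- list(
    promoter2kb = ir(prom$start, prom$end),
    utr5 = ir(genes$utr5_start, genes$utr5_end),
    coding = ir(genes$cds_start, genes$cds_end),
    downstream = ir(down_start, down_end))
  taken <- IRanges::IRanges()
  for (nm in names(cats)) {
    cats[[nm]] <- IRanges::setdiff(cats[[nm]], taken)
    taken <- IRanges::reduce(c(taken, cats[[nm]]))
  }
  cats$intergenic <- IRanges::setdiff(
    IRanges::IRanges(1L, genome_length), taken)
  cats
}

#' Classify peaks by the genomic feature at their summit
#'
#' Assigns each peak summit to one of `promoter2kb` (2 kb upstream of the
#' TSS, strand-aware), `utr5`, `coding`, `downstream` (2 kb past the TES),
#' or `intergenic`, with that precedence, so the categories partition the
#' peaks. Whole-peak bp-overlap classification (majority category over the
#' peak interval) is available with `by = "overlap"`.
#'
#' @param peaks A `peak_set` with summits (replicate-level or concordant).
#' @param genes Gene-model data.frame.
#' @param genome_length Genome size in bp.
#' @param downstream_width Downstream flank length in bp.
#' @param by `"summit"` (default) or `"overlap"`.
#' @return Character vector of categories, one per peak.
#' @export
classify_feature <- function(peaks, genes, genome_length,
                             downstream_width = 2000L,
                             by = c("summit", "overlap")) {
  by <- match.arg(by)
  cats <- feature_partition(genes, genome_length,
                            downstream_width = downstream_width)
  if (by == "summit") {
    pos <- IRanges::IRanges(peaks$summit + 1L, peaks$summit + 1L)
  } else {
    pos <- IRanges::IRanges(peaks$start + 1L, peaks$end)
  }
  out <- rep("intergenic", nrow(peaks))
  if (by == "summit") {
    # the partition is disjoint: each summit hits exactly one category
    for (nm in setdiff(names(cats), "intergenic")) {
      ov <- IRanges::findOverlaps(pos, cats[[nm]])
      out[S4Vectors::queryHits(ov)] <- nm
    }
  } else {
    # majority bp-overlap over the peak interval, precedence on ties
    score <- rep(0, nrow(peaks))
    for (nm in rev(setdiff(names(cats), "intergenic"))) {
      ov <- IRanges::findOverlaps(pos, cats[[nm]])
      if (length(ov) == 0) next
      w <- tapply(
        IRanges::width(IRanges::pintersect(
          pos[S4Vectors::queryHits(ov)],
          cats[[nm]][S4Vectors::subjectHits(ov)])),
        S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(w))
      better <- w >= score[idx]
      out[idx[better]] <- nm
      score[idx[better]] <- w[better]
    }
  }
  out
}

#' Genomic-feature enrichment of peaks against genome composition
#'
#' Compares the peak-summit feature composition with the genome's bp
#' composition: per category, a two-sided Fisher's exact test on the 2x2
#' table of (peaks in category vs not) against (genome-composition expected
#' counts scaled to the peak total).
#'
#' @param peaks A `peak_set` with summits.
#' @param genes Gene-model data.frame.
#' @param genome_length Genome size in bp.
#' @return data.frame with `category`, `peak_count`, `genome_fraction`,
#'   `odds_ratio`, `fisher_p`; genome fractions sum to 1.
#' @export
feature_enrichment <- function(peaks, genes, genome_length) {
  check_that(nrow(peaks) >= 1, "feature_enrichment needs >= 1 peak")
  cats <- feature_partition(genes, genome_length)
  frac <- vapply(cats, function(x) sum(IRanges::width(x)), numeric(1)) /
    genome_length
  cls <- classify_feature(peaks, genes, genome_length)
  total <- nrow(peaks)
  out <- data.frame(category = names(cats),
                    peak_count = as.integer(
                      table(factor(cls, levels = names(cats)))),
                    genome_fraction = as.numeric(frac),
                    odds_ratio = NA_real_, fisher_p = NA_real_,
                    stringsAsFactors = FALSE)
  drop <- out$genome_fraction == 0
  if (any(drop)) {
    warning("excluding categories with zero genome bp: ",
            paste(out$category[drop], collapse = ", "))
  }
  for (i in which(!drop)) {
    expected <- round(out$genome_fraction[i] * total)
    tab <- matrix(c(out$peak_count[i], total - out$peak_count[i],
                    expected, total - expected), nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab)
    out$odds_ratio[i] <- unname(ft$estimate)
    out$fisher_p[i] <- ft$p.value
  }
  out[!drop, , drop = FALSE]
}
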