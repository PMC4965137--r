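#' Per-base fragment pileup
#'
#' The value at position x is the number of fragments covering x.
#'
#' @param fs A deduplicated, depth-normalized [fragment_set()].
#' @return A [coverage_track()] with `bin_size = 1` spanning the genome.
#' @examples
#' f <- data.frame(chrom = "chr1", start = 10L, end = 20L, strand = "+")
#' fs <- fragment_set("s", "P1", "ZT3", 1, "ChIP", f, 30)
#' sum(fragment_pileup(fs)$values)
#' @export
fragment_pileup <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  f <- fs$fragments
  cov <- IRanges::coverage(
    IRanges::IRanges(start = f$start + 1L, end = f$end),
    width = fs$genome_length)
  coverage_track(chrom = if (nrow(f) > 0) f$chrom[1] else "chr1",
                 bin_size = 1L, values = as.integer(cov))
}

#' Call enriched peaks with a Poisson local-background test
#'
#' Re-implements the MACS-style enrichment test: each position's treatment
#' count is tested against a Poisson null whose rate is the local background
#' `lambda_local = max(lambda_genome, lambda_1kb, lambda_5kb, lambda_10kb)`
#' estimated from the input (control) coverage in windows centered on the
#' position. Positions with upper-tail probability `P(X >= k)` below `p_cut`
#' are merged into peaks when separated by at most `merge_gap` bp; peaks
#' shorter than `min_length` are dropped. The summit is the leftmost
#' treatment-pileup maximum within the peak; the reported `p_value` is the
#' minimum per-base p-value and `fold_enrichment` the summit count over the
#' summit's local lambda.
#'
#' Treatment and control are assumed depth-matched (run [downsample_all()]
#' first). If the control track is all-zero the background is estimated from
#' the treatment track itself, with a warning.
#'
#' @param treat,control Per-base [coverage_track()]s of equal length.
#' @param p_cut Per-base Poisson p-value cutoff (default `1e-3`).
#' @param merge_gap Maximum gap (bp) between significant stretches merged
#'   into one peak.
#' @param min_length Minimum peak length (bp).
#' @param windows Local-background window sizes (bp).
#' @param genotype,zt Optional sample provenance stamped on the peaks.
#' @return A `peak_set`: data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `summit`, `p_value`, `fold_enrichment`,
#'   `genotype`, `zt`, and attribute `source = "replicate-level"`.
#' @export
call_peaks <- function(treat, control, p_cut = 1e-3, merge_gap = 100L,
                       min_length = 150L, windows = c(1000L, 5000L, 10000L),
                       genotype = NA_character_, zt = NA_character_) {
  stopifnot(inherits(treat, "coverage_track"),
            inherits(control, "coverage_track"),
            treat$bin_size == 1L, control$bin_size == 1L)
  check_that(length(treat$values) == length(control$values),
             "treatment and control tracks must have equal length")
  check_rate(p_cut, "p_cut")

  ep <- enrichment_pvalues(treat, control, windows)
  lam <- ep$lambda
  k <- treat$values
  pv <- ep$p
  sig <- which(pv < p_cut & k > 0)

  peaks <- merge_significant(sig, merge_gap, min_length)
  if (nrow(peaks) == 0) {
    return(peak_set(empty_peak_table(genotype, zt), source = "replicate-level"))
  }
  summit <- integer(nrow(peaks))
  p_peak <- numeric(nrow(peaks))
  fold <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    span <- (peaks$start[i] + 1L):peaks$end[i]  # 1-based index into tracks
    summit[i] <- span[which.max(k[span])] - 1L  # leftmost argmax, 0-based
    p_peak[i] <- max(min(pv[span]), .Machine$double.xmin)
    fold[i] <- k[summit[i] + 1L] / max(lam[summit[i] + 1L],
                                       .Machine$double.eps)
  }
  peak_set(data.frame(
    chrom = treat$chrom, start = peaks$start, end = peaks$end,
    summit = summit, p_value = p_peak, fold_enrichment = fold,
    genotype = genotype, zt = zt, stringsAsFactors = FALSE),
    source = "replicate-level")
}

#' Per-position Poisson enrichment p-values
#'
#' The per-base test underlying [call_peaks()]: at each position the
#' treatment count k is scored with the Poisson upper tail `P(X >= k)`
#' under the local background rate
#' `lambda_local = max(lambda_genome, lambda_w)` over the window sizes `w`,
#' each lambda estimated from the control coverage (centered running
#' means). If the control is all-zero the treatment itself estimates the
#' background, with a warning.
#'
#' @param treat,control Per-base [coverage_track()]s of equal length.
#' @param windows Local-background window sizes (bp).
#' @return A list with `p` (upper-tail p-value per position) and `lambda`
#'   (the local rate per position).
#' @export
enrichment_pvalues <- function(treat, control,
                               windows = c(1000L, 5000L, 10000L)) {
  bg <- control$values
  if (sum(bg) == 0) {
    warning("control track is all-zero; estimating background from treatment")
    bg <- treat$values
  }
  lam <- local_lambda(bg, windows)
  list(p = ppois(treat$values - 1, lam, lower.tail = FALSE), lambda = lam)
}

# max over genome-wide rate and centered running means of several windows
local_lambda <- function(bg, windows) {
  L <- length(bg)
  lam <- rep(mean(bg), L)
  cs <- c(0, cumsum(bg))
  pos <- seq_len(L)
  for (w in windows) {
    half <- w %/% 2
    lo <- pmax(pos - half, 1L)
    hi <- pmin(pos + half, L)
    lam <- pmax(lam, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  }
  lam
}

# merge 1-based significant positions into 0-based half-open intervals
merge_significant <- function(sig, merge_gap, min_length) {
  if (length(sig) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  new_run <- c(TRUE, diff(sig) > merge_gap + 1L)
  run_id <- cumsum(new_run)
  start <- tapply(sig, run_id, min) - 1L
  end <- tapply(sig, run_id, max)
  keep <- (end - start) >= min_length
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]))
}

peak_set <- function(df, source = c("replicate-level", "concordant", "master")) {
  source <- match.arg(source)
  attr(df, "source") <- source
  class(df) <- c("peak_set", "data.frame")
  df
}

empty_peak_table <- function(genotype = NA_character_, zt = NA_character_) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), p_value = numeric(),
             fold_enrichment = numeric(),
             genotype = character(), zt = character(), stringsAsFactors = FALSE)
}

#' Source label of a peak set
#' @param x A `peak_set`.
#' @return `"replicate-level"`, `"concordant"`, or `"master"`.
#' @export
peak_source <- function(x) attr(x, "source")

#' Replicate-concordant peaks
#'
#' Keeps peaks supported by both biological replicates: every `rep1` peak
#' with >= 1 bp overlap (configurable minimum fraction) of some `rep2` peak
#' is retained, with coordinates replaced by the union span of the
#' overlapping pair; chained unions are reduced to non-overlapping
#' intervals. Membership is symmetric in the replicates.
#'
#' @param rep1,rep2 `peak_set`s from the two replicates of one
#'   (genotype, ZT).
#' @param min_overlap_frac Minimum reciprocal overlap fraction required
#'   (default 0 = any overlap).
#' @return A `peak_set` with `source = "concordant"`; `p_value` is the
#'   minimum and `fold_enrichment` the maximum over contributing peaks, and
#'   the summit is taken from the contributing peak with the smallest
#'   p-value.
#' @export
concordant_peaks <- function(rep1, rep2, min_overlap_frac = 0) {
  ir1 <- IRanges::IRanges(rep1$start + 1L, rep1$end)
  ir2 <- IRanges::IRanges(rep2$start + 1L, rep2$end)
  hits <- IRanges::findOverlaps(ir1, ir2)
  if (min_overlap_frac > 0 && length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      ir1[S4Vectors::queryHits(hits)], ir2[S4Vectors::subjectHits(hits)]))
    w1 <- IRanges::width(ir1[S4Vectors::queryHits(hits)])
    w2 <- IRanges::width(ir2[S4Vectors::subjectHits(hits)])
    hits <- hits[ov / w1 >= min_overlap_frac & ov / w2 >= min_overlap_frac]
  }
  if (length(hits) == 0) {
    return(peak_set(empty_peak_table(), source = "concordant"))
  }
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  union_start <- pmin(rep1$start[q], rep2$start[s])
  union_end <- pmax(rep1$end[q], rep2$end[s])
  merged <- IRanges::reduce(IRanges::IRanges(union_start + 1L, union_end))

  contrib <- rbind(
    rep1[unique(q), c("start", "end", "summit", "p_value", "fold_enrichment")],
    rep2[unique(s), c("start", "end", "summit", "p_value", "fold_enrichment")])
  cm <- IRanges::findOverlaps(
    IRanges::IRanges(contrib$start + 1L, contrib$end), merged)
  out <- data.frame(
    chrom = rep1$chrom[1], start = IRanges::start(merged) - 1L,
    end = IRanges::end(merged), summit = NA_integer_,
    p_value = NA_real_, fold_enrichment = NA_real_,
    genotype = if (nrow(rep1) > 0) rep1$genotype[1] else NA_character_,
    zt = if (nrow(rep1) > 0) rep1$zt[1] else NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    members <- contrib[S4Vectors::queryHits(cm)[S4Vectors::subjectHits(cm) == i], ]
    best <- order(members$p_value, members$summit)[1]
    out$summit[i] <- members$summit[best]
    out$p_value[i] <- min(members$p_value)
    out$fold_enrichment[i] <- max(members$fold_enrichment)
  }
  peak_set(out, source = "concordant")
}

#' Per-genotype master peaks across time points
#'
#' Merges the replicate-concordant peaks obtained at each zeitgeber time
#' into one non-redundant master-peak list per genotype (interval union);
#' each master peak records which ZTs contributed.
#'
#' @param per_zt Named list (names = ZT labels) of concordant `peak_set`s.
#' @return A `peak_set` with `source = "master"` and a `zts` column
#'   (comma-separated contributing ZTs).
#' @export
master_peaks <- function(per_zt) {
  stopifnot(is.list(per_zt), !is.null(names(per_zt)))
  nonempty <- per_zt[vapply(per_zt, nrow, integer(1)) > 0]
  if (length(nonempty) == 0) {
    out <- cbind(empty_peak_table(), zts = character(0))
    return(peak_set(out, source = "master"))
  }
  all_ir <- do.call(c, unname(lapply(nonempty, function(p)
    IRanges::IRanges(p$start + 1L, p$end))))
  merged <- IRanges::reduce(all_ir)
  zts <- character(length(merged))
  for (z in names(nonempty)) {
    p <- nonempty[[z]]
    hit <- unique(S4Vectors::subjectHits(IRanges::findOverlaps(
      IRanges::IRanges(p$start + 1L, p$end), merged)))
    zts[hit] <- ifelse(zts[hit] == "", z, paste(zts[hit], z, sep = ","))
  }
  g <- unique(na.omit(vapply(nonempty, function(p)
    if (nrow(p) > 0) p$genotype[1] else NA_character_, character(1))))
  peak_set(data.frame(
    chrom = nonempty[[1]]$chrom[1],
    start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
    summit = NA_integer_, p_value = NA_real_, fold_enrichment = NA_real_,
    genotype = if (length(g) == 1) g else NA_character_, zt = NA_character_,
    zts = zts, stringsAsFactors = FALSE), source = "master")
}

#' Input-subtracted signal track
#'
#' Pointwise `treatment - control` coverage floored at zero, the
#' visualization-ready representation of ChIP signal on a common scale
#' across depth-matched samples.
#'
#' @param treat,control Depth-matched [coverage_track()]s of equal binning.
#' @return A [coverage_track()].
#' @export
input_subtracted_track <- function(treat, control) {
  stopifnot(inherits(treat, "coverage_track"),
            inherits(control, "coverage_track"))
  check_that(treat$bin_size == control$bin_size &&
               length(treat$values) == length(control$values),
             "tracks must share bin size and length")
  coverage_track(treat$chrom, treat$bin_size,
                 pmax(treat$values - control$values, 0))
}
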