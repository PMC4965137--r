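#' Construct a fragment set
#'
#' A `fragment_set` holds the mapped, paired-end-derived fragment intervals
#' of one sample (one genotype x zeitgeber time x replicate x
#' treatment combination), the unit of depth normalization and pileup.
#' Intervals are 0-based, half-open (`start < end`).
#'
#' @param sample_id Sample identifier.
#' @param genotype,zt,replicate,treatment Sample annotations (`treatment` is
#'   `"ChIP"` or `"input"`).
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome_length Genome size in bp (used by coverage operations).
#' @return An object of class `fragment_set`.
#' @examples
#' fs <- fragment_set("s1", "P1", "ZT3", 1, "ChIP",
#'   data.frame(chrom = "chr1", start = 0L, end = 400L, strand = "+"),
#'   genome_length = 1000L)
#' n_fragments(fs)
#' @export
fragment_set <- function(sample_id, genotype, zt, replicate, treatment,
                         fragments, genome_length) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end", "strand") %in% names(fragments)))
  if (nrow(fragments) > 0) {
    check_that(all(fragments$start < fragments$end),
               "fragment intervals must satisfy start < end")
    check_that(all(fragments$start >= 0) &&
                 all(fragments$end <= genome_length),
               "fragment coordinates must lie within [0, genome_length)")
  }
  structure(list(sample_id = sample_id, genotype = genotype, zt = zt,
                 replicate = as.integer(replicate), treatment = treatment,
                 fragments = fragments,
                 genome_length = as.integer(genome_length)),
            class = "fragment_set")
}

empty_fragment_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Number of fragments in a fragment set
#' @param fs A [fragment_set()].
#' @return Integer fragment count.
#' @export
n_fragments <- function(fs) nrow(fs$fragments)

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set %s (%s %s rep%d %s): %d fragments\n",
              x$sample_id, x$genotype, x$zt, x$replicate, x$treatment,
              n_fragments(x)))
  invisible(x)
}

#' Remove PCR-duplicate fragments
#'
#' Drops fragments identical in `(chrom, start, end, strand)` — the
#' fragment-space equivalent of paired-end `samtools rmdup` — keeping the
#' first occurrence and preserving input order otherwise. Idempotent.
#'
#' @param fs A [fragment_set()].
#' @return The deduplicated [fragment_set()].
#' @examples
#' f <- data.frame(chrom = "chr1", start = c(0, 0, 10), end = c(5, 5, 20),
#'                 strand = "+")
#' fs <- fragment_set("s", "P1", "ZT3", 1, "ChIP", f, 100)
#' n_fragments(deduplicate(fs))
#' @export
deduplicate <- function(fs) {
  stopifnot(inherits(fs, "fragment_set"))
  f <- fs$fragments
  if (nrow(f) == 0) return(fs)
  keep <- !duplicated(f[c("chrom", "start", "end", "strand")])
  fs$fragments <- f[keep, , drop = FALSE]
  rownames(fs$fragments) <- NULL
  fs
}

#' Down-sample all samples to a common depth
#'
#' Equalizes sequencing depth across samples by drawing, uniformly without
#' replacement, the same number of fragments from every sample: the smallest
#' deduplicated fragment count among the samples being normalized (e.g.
#' samples of 4, 5, 6 and 7 million fragments are all down-sampled to
#' 4 million). Samples already at the minimum pass through unchanged.
#'
#' @param samples A list of deduplicated [fragment_set()] objects.
#' @param seed Integer seed for the subsampling draws.
#' @param chip_only If `TRUE`, the common minimum is computed over ChIP
#'   samples only and input samples are left untouched; by default ChIP and
#'   input samples are pooled into a single min-count normalization.
#' @return The list with every (normalized) sample at the common depth.
#' @examples
#' mk <- function(id, n) fragment_set(id, "P1", "ZT3", 1, "ChIP",
#'   data.frame(chrom = "chr1", start = seq_len(n) - 1L, end = seq_len(n),
#'              strand = "+"), genome_length = n + 1L)
#' out <- downsample_all(list(mk("a", 40), mk("b", 70)), seed = 1)
#' vapply(out, n_fragments, integer(1))
#' @export
downsample_all <- function(samples, seed = 1L, chip_only = FALSE) {
  stopifnot(is.list(samples), length(samples) > 0)
  is_chip <- vapply(samples, function(s) s$treatment == "ChIP", logical(1))
  pool <- if (chip_only) which(is_chip) else seq_along(samples)
  counts <- vapply(samples[pool], n_fragments, integer(1))
  empty <- counts == 0
  if (any(empty)) {
    ids <- vapply(samples[pool][empty], function(s) s$sample_id, character(1))
    stop("cannot down-sample: empty sample(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  target <- min(counts)
  withr::with_seed(seed, {
    for (i in pool) {
      n <- n_fragments(samples[[i]])
      if (n > target) {
        keep <- sort(sample.int(n, target))
        samples[[i]]$fragments <-
          samples[[i]]$fragments[keep, , drop = FALSE]
        rownames(samples[[i]]$fragments) <- NULL
      }
    }
  })
  samples
}

#' Coverage track constructor
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (`1` for per-base pileup).
#' @param values Numeric vector of per-bin values covering the genome from
#'   position 0.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, bin_size, values) {
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 values = values), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s: %d bins of %d bp (total %g)\n",
              x$chrom, length(x$values), x$bin_size, sum(x$values)))
  invisible(x)
}

#' Bin fragment coverage by midpoint
#'
#' Counts, per consecutive genomic bin (default 1 kb), the fragments whose
#' midpoint falls in the bin, so bin values sum to the fragment count.
#' Overlap-weighted counting (each fragment contributing its bp overlap with
#' the bin divided by its length) is available via `method = "overlap"`.
#'
#' @param fs A [fragment_set()].
#' @param bin_size Bin width in bp, >= 1.
#' @param method `"midpoint"` (default) or `"overlap"`.
#' @return A [coverage_track()] spanning the genome.
#' @examples
#' f <- data.frame(chrom = "chr1", start = 100L, end = 300L, strand = "+")
#' fs <- fragment_set("s", "P1", "ZT3", 1, "ChIP", f, 5000)
#' bin_coverage(fs, 1000)$values
#' @export
bin_coverage <- function(fs, bin_size = 1000L,
                         method = c("midpoint", "overlap")) {
  stopifnot(inherits(fs, "fragment_set"), bin_size >= 1)
  method <- match.arg(method)
  n_bins <- ceiling(fs$genome_length / bin_size)
  f <- fs$fragments
  if (method == "midpoint") {
    mid <- (f$start + f$end) %/% 2
    idx <- pmin(n_bins, mid %/% bin_size + 1L)
    vals <- tabulate(idx, nbins = n_bins)
  } else {
    vals <- numeric(n_bins)
    if (nrow(f) > 0) {
      len <- f$end - f$start
      for (i in seq_len(nrow(f))) {
        b0 <- f$start[i] %/% bin_size
        b1 <- (f$end[i] - 1L) %/% bin_size
        for (b in b0:b1) {
          lo <- max(f$start[i], b * bin_size)
          hi <- min(f$end[i], (b + 1) * bin_size)
          vals[b + 1L] <- vals[b + 1L] + (hi - lo) / len[i]
        }
      }
    }
  }
  coverage_track(chrom = if (nrow(f) > 0) f$chrom[1] else "chr1",
                 bin_size = bin_size, values = vals)
}

#' Replicate concordance by binned-coverage correlation
#'
#' Pearson correlation between two coverage tracks binned identically
#' (1-kb bins by convention), the replicate-concordance QC used before peak
#' calling, with a pass/fail call against a correlation threshold.
#'
#' @param a,b [coverage_track()] objects with equal `bin_size` and length.
#' @param qc_threshold Minimum correlation considered concordant.
#' @return A list with `r` (Pearson correlation) and `pass` (logical).
#' @examples
#' a <- coverage_track("chr1", 1000, c(1, 4, 2, 8))
#' replicate_correlation(a, a)$r
#' @export
replicate_correlation <- function(a, b, qc_threshold = 0.9) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  check_that(a$bin_size == b$bin_size && length(a$values) == length(b$values),
             "tracks must share bin size and bin count")
  if (sd(a$values) == 0 || sd(b$values) == 0) {
    stop("undefined correlation: zero-variance coverage track", call. = FALSE)
  }
  r <- cor(a$values, b$values)
  list(r = r, pass = r >= qc_threshold)
}
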