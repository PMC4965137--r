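#' Extract peak sequences from a genome
#'
#' @param peaks A `peak_set` (0-based half-open intervals).
#' @param genome A [Biostrings::DNAStringSet] with the chromosome sequences.
#' @return A [Biostrings::DNAStringSet], one sequence per peak.
#' @export
peak_sequences <- function(peaks, genome) {
  check_that(all(peaks$chrom %in% names(genome)),
             "peak chromosome(s) absent from genome")
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(peaks) > 0) {
    check_that(all(peaks$start >= 0) &&
                 all(peaks$end <= lens[peaks$chrom]),
               "peak coordinates outside genome bounds")
  }
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(peaks)), function(i)
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i])), character(1)))
  names(out) <- sprintf("peak%d", seq_len(nrow(peaks)))
  out
}

#' Scan peaks for consensus binding motifs
#'
#' Exact string matching of each consensus (and its reverse complement, so
#' both strands are covered) against the peak sequences.
#'
#' @param peaks A `peak_set`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param motifs data.frame with `name` and `consensus` columns; defaults
#'   to [known_motifs()] (EE, CBS, Dof).
#' @return A list with `occurrences` (integer matrix, peaks x motifs: hit
#'   counts summed over strands) and `fraction` (named vector: fraction of
#'   peaks with >= 1 hit per motif).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTTAAATATCTTTTGGGG"))
#' pk <- data.frame(chrom = "chr1", start = 0L, end = 18L)
#' scan_motifs(pk, g)$fraction
#' @export
scan_motifs <- function(peaks, genome, motifs = known_motifs()) {
  seqs <- peak_sequences(peaks, genome)
  occ <- motif_hits(seqs, motifs)
  list(occurrences = occ,
       fraction = colMeans(occ >= 1))
}

motif_hits <- function(seqs, motifs) {
  occ <- matrix(0L, length(seqs), nrow(motifs),
                dimnames = list(names(seqs), motifs$name))
  for (j in seq_len(nrow(motifs))) {
    pat <- motifs$consensus[j]
    occ[, j] <- Biostrings::vcountPattern(pat, seqs) +
      Biostrings::vcountPattern(revcomp_string(pat), seqs)
  }
  occ
}

#' Empirical motif enrichment against dinucleotide-shuffled background
#'
#' Shuffles each peak sequence with an Altschul-Erikson dinucleotide-
#' preserving shuffle (exact dinucleotide counts retained), recomputes the
#' per-motif hit fraction, and reports the add-one-corrected empirical
#' p-value: the fraction of shuffled sets whose hit fraction is at least
#' the observed one.
#'
#' @param peaks A `peak_set`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param motifs data.frame of consensus motifs (default [known_motifs()]).
#' @param n_shuffles Number of shuffled background sets (>= 100 advised).
#' @param seed Integer seed.
#' @return data.frame with `motif`, `observed_fraction`, `shuffled_mean`,
#'   `p` where `p = (1 + #{shuffles >= observed}) / (n_shuffles + 1)`.
#' @export
motif_enrichment <- function(peaks, genome, motifs = known_motifs(),
                             n_shuffles = 100L, seed = 1L) {
  seqs <- peak_sequences(peaks, genome)
  observed <- colMeans(motif_hits(seqs, motifs) >= 1)
  chars <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
  ge <- withr::with_seed(seed, {
    ge <- matrix(0L, n_shuffles, nrow(motifs),
                 dimnames = list(NULL, motifs$name))
    shuffled_sum <- numeric(nrow(motifs))
    for (b in seq_len(n_shuffles)) {
      shuf <- Biostrings::DNAStringSet(vapply(
        chars, function(x) paste(dinucleotide_shuffle(x), collapse = ""),
        character(1)))
      frac <- colMeans(motif_hits(shuf, motifs) >= 1)
      shuffled_sum <- shuffled_sum + frac
      ge[b, ] <- as.integer(frac >= observed)
    }
    list(ge = ge, mean = shuffled_sum / n_shuffles)
  })
  data.frame(motif = motifs$name,
             observed_fraction = as.numeric(observed),
             shuffled_mean = as.numeric(ge$mean),
             p = (1 + colSums(ge$ge)) / (n_shuffles + 1),
             stringsAsFactors = FALSE)
}

# Altschul-Erikson shuffle of a character vector: permutes the sequence
# while preserving the exact multiset of (overlapping) dinucleotides.
dinucleotide_shuffle <- function(x) {
  n <- length(x)
  if (n <= 2L) return(x)
  letters_ <- unique(x)
  v <- match(x, letters_)
  m <- length(letters_)
  s1 <- v[1]; sn <- v[n]
  edges <- split(v[-1], v[-n])  # adjacency lists keyed by source vertex

  sources <- as.integer(names(edges))
  # pick per-vertex terminal edges forming a tree into the walk's end vertex
  repeat {
    last <- rep(NA_integer_, m)
    for (s in sources) {
      if (s == sn) next
      last[s] <- edges[[as.character(s)]][sample.int(
        length(edges[[as.character(s)]]), 1L)]
    }
    ok <- TRUE
    for (s in sources) {
      if (s == sn) next
      cur <- s; steps <- 0L
      while (!is.na(last[cur]) && cur != sn && steps <= m) {
        cur <- last[cur]; steps <- steps + 1L
      }
      if (cur != sn) { ok <- FALSE; break }
    }
    if (ok) break
  }

  adj <- vector("list", m)
  ptr <- integer(m)
  for (s in sources) {
    e <- edges[[as.character(s)]]
    if (s != sn) {
      drop_one <- match(last[s], e)
      e <- e[-drop_one]
    }
    e <- e[sample.int(length(e))]
    if (s != sn) e <- c(e, last[s])
    adj[[s]] <- e
    ptr[s] <- 1L
  }

  out <- integer(n)
  out[1] <- s1
  cur <- s1
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  letters_[out]
}

#' GO-term enrichment of a target set
#'
#' Upper-tail hypergeometric test per term against a flat gene-to-term
#' annotation, with Benjamini-Hochberg correction across the tested terms.
#' Terms annotating fewer than `min_term_size` universe genes are skipped.
#'
#' @param target_genes Character vector of target gene ids (subset of the
#'   universe).
#' @param universe_genes Character vector of all annotated-universe gene
#'   ids.
#' @param annotation data.frame with `gene_id`, `term_id`.
#' @param min_term_size Minimum universe genes per tested term.
#' @return data.frame ordered by `p_hyper`: `term_id`, `k` (targets with
#'   term), `K` (universe with term), `n` (targets), `N` (universe),
#'   `p_hyper`, `fdr_bh`.
#' @export
go_enrichment <- function(target_genes, universe_genes, annotation,
                          min_term_size = 3L) {
  check_that(length(universe_genes) > 0, "empty gene universe")
  universe_genes <- unique(universe_genes)
  target_genes <- unique(target_genes)
  check_that(all(target_genes %in% universe_genes),
             "target genes must be a subset of the universe")
  ann <- annotation[annotation$gene_id %in% universe_genes, , drop = FALSE]
  ann <- unique(ann[c("gene_id", "term_id")])
  N <- length(universe_genes)
  n <- length(target_genes)
  K_all <- table(ann$term_id)
  terms <- names(K_all)[K_all >= min_term_size]
  if (length(terms) == 0) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_hyper = numeric(),
                      fdr_bh = numeric(), stringsAsFactors = FALSE))
  }
  k <- vapply(terms, function(t)
    sum(ann$gene_id[ann$term_id == t] %in% target_genes), integer(1))
  K <- as.integer(K_all[terms])
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N,
                    p_hyper = p, fdr_bh = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_hyper, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
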