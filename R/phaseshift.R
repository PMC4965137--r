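#' Per-ZT replicate binding abundance of one target
#'
#' Abundance of peak enrichment is the pseudocounted ratio of treatment to
#' control fragment counts within the target's master-peak interval(s):
#' `(treatment + pseudocount) / (control + pseudocount)`, per replicate and
#' zeitgeber time.
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open), the
#'   master-peak interval(s) assigned to the gene.
#' @param samples Named list of [fragment_set()]s as produced by
#'   [simulate_chip_fragments()] (names `"<genotype>_<ZT>_rep<k>_<ChIP|input>"`).
#' @param genotype Genotype whose samples to use.
#' @param replicates Number of replicates expected per ZT.
#' @param pseudocount Added to both counts.
#' @return data.frame with `zt`, `replicate`, `treat`, `control`,
#'   `abundance`.
#' @export
target_abundance <- function(intervals, samples, genotype, replicates = 2L,
                             pseudocount = 1) {
  ir <- IRanges::IRanges(intervals$start + 1L, intervals$end)
  out <- expand.grid(zt = ZT_LEVELS, replicate = seq_len(replicates),
                     stringsAsFactors = FALSE)
  out$treat <- NA_real_
  out$control <- NA_real_
  for (i in seq_len(nrow(out))) {
    keys <- sample_key(genotype, out$zt[i], out$replicate[i],
                       c("ChIP", "input"))
    missing <- keys[!keys %in% names(samples)]
    if (length(missing) > 0) {
      stop("missing sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    cnt <- vapply(keys, function(k) {
      f <- samples[[k]]$fragments
      sum(IRanges::countOverlaps(
        IRanges::IRanges(f$start + 1L, f$end), ir) > 0)
    }, numeric(1))
    out$treat[i] <- cnt[1]
    out$control[i] <- cnt[2]
  }
  out$abundance <- (out$treat + pseudocount) / (out$control + pseudocount)
  out
}

#' Assign a binding phase from per-ZT abundances
#'
#' Implements the phase criteria: a one-way ANOVA (equal-variance) across
#' the three ZT groups must reject at `alpha`, and the top time point must
#' be strictly separated from the runner-up (two-sample Student's t at the
#' same `alpha`; Tukey's HSD available via `tie_method`). Targets failing
#' the ANOVA, or showing the same abundance at two or more time points, are
#' excluded from the phase-shift analysis.
#'
#' Abundances (treatment/control ratios) are log2-transformed before
#' testing by default, which stabilizes the variance of the ratio.
#'
#' @param abund data.frame with columns `zt` and `abundance` (>= 2
#'   replicates per ZT), e.g. from [target_abundance()].
#' @param alpha Significance cutoff for the ANOVA and the tie rule.
#' @param log Test on log2 abundances (default `TRUE`).
#' @param tie_method `"t"` (Student's t on the top two ZTs, default) or
#'   `"tukey"` (Tukey HSD adjusted p for that comparison).
#' @return A list with `phase` (`"ZT3"`, `"ZT9"`, `"ZT15"`, or
#'   `"excluded"`), `anova_p`, `tie_p`, and `reason` (`"ok"`, `"anova"`,
#'   `"tie"`, or `"degenerate"`).
#' @examples
#' ab <- data.frame(zt = rep(c("ZT3", "ZT9", "ZT15"), each = 2),
#'                  abundance = c(30, 29, 10, 11, 10, 9))
#' assign_phase(ab)$phase
#' @export
assign_phase <- function(abund, alpha = 0.05, log = TRUE,
                         tie_method = c("t", "tukey")) {
  tie_method <- match.arg(tie_method)
  stopifnot(all(c("zt", "abundance") %in% names(abund)))
  check_that(all(table(abund$zt) >= 2), "need >= 2 replicates per ZT")
  x <- if (log) log2(pmax(abund$abundance, .Machine$double.eps))
       else abund$abundance
  g <- factor(abund$zt, levels = ZT_LEVELS)
  means <- tapply(x, g, mean)
  sds <- tapply(x, g, sd)

  excluded <- function(reason, anova_p = NA_real_, tie_p = NA_real_) {
    list(phase = "excluded", anova_p = anova_p, tie_p = tie_p,
         reason = reason)
  }
  if (all(sds == 0)) {
    if (max(means) - min(means) == 0) return(excluded("degenerate"))
    anova_p <- 0
  } else {
    anova_p <- oneway.test(x ~ g, var.equal = TRUE)$p.value
  }
  if (is.na(anova_p) || anova_p >= alpha) return(excluded("anova", anova_p))

  ord <- order(means, decreasing = TRUE)
  top <- levels(g)[ord[1]]
  runner <- levels(g)[ord[2]]
  xt <- x[g == top]; xr <- x[g == runner]
  if (sd(xt) == 0 && sd(xr) == 0) {
    tie_p <- if (mean(xt) == mean(xr)) 1 else 0
  } else if (tie_method == "t") {
    tie_p <- t.test(xt, xr, var.equal = TRUE)$p.value
  } else {
    tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
    hit <- vapply(rownames(tk), function(r)
      setequal(strsplit(r, "-")[[1]], c(top, runner)), logical(1))
    tie_p <- tk[hit, "p adj"][1]
  }
  if (is.na(tie_p) || tie_p >= alpha) return(excluded("tie", anova_p, tie_p))
  list(phase = top, anova_p = anova_p, tie_p = tie_p, reason = "ok")
}

#' Partition target-gene sets by genotype class
#'
#' Splits targets into genes shared by all four genotypes, specific to the
#' hybrids, specific to the inbreds, and the remainder. By default the
#' specificity classes use union semantics: a gene is hybrid-specific when
#' it is a target in either hybrid and in neither inbred (and vice versa);
#' `semantics = "intersection"` requires it in both members of the class.
#'
#' @param targets Named list of character vectors of target gene ids with
#'   names `P1`, `P2`, `H12`, `H21`.
#' @param semantics `"union"` (default) or `"intersection"`.
#' @return A list with `shared_all`, `hybrid_specific`, `inbred_specific`,
#'   `other` (disjoint character vectors).
#' @examples
#' t <- list(P1 = c("a", "b"), P2 = c("a"), H12 = c("a", "c"), H21 = "a")
#' partition_targets(t)$shared_all
#' @export
partition_targets <- function(targets, semantics = c("union", "intersection")) {
  semantics <- match.arg(semantics)
  check_that(all(GENOTYPES %in% names(targets)),
             "'targets' must contain P1, P2, H12 and H21")
  hyb <- if (semantics == "union") union(targets$H12, targets$H21)
         else intersect(targets$H12, targets$H21)
  inb <- if (semantics == "union") union(targets$P1, targets$P2)
         else intersect(targets$P1, targets$P2)
  hyb_any <- union(targets$H12, targets$H21)
  inb_any <- union(targets$P1, targets$P2)
  shared_all <- Reduce(intersect, targets[GENOTYPES])
  hybrid_specific <- setdiff(hyb, inb_any)
  inbred_specific <- setdiff(inb, hyb_any)
  all_targets <- union(hyb_any, inb_any)
  other <- setdiff(all_targets,
                   c(shared_all, hybrid_specific, inbred_specific))
  list(shared_all = sort(shared_all),
       hybrid_specific = sort(hybrid_specific),
       inbred_specific = sort(inbred_specific),
       other = sort(other))
}

#' Fisher's exact test for a temporal shift between genotype groups
#'
#' Tests whether the proportion of targets phased at `zt` differs between
#' two genotype groups (e.g. hybrids vs inbreds, pooled across the group's
#' genotypes): a two-sided Fisher's exact test on the 2x2 table of
#' (phase == zt vs phase != zt) x (group A vs group B). Excluded targets
#' are dropped.
#'
#' @param phase_table data.frame with `gene_id`, `genotype`, `phase` (as
#'   built by [build_phase_tables()]).
#' @param group_a,group_b Character vectors of genotypes.
#' @param zt The zeitgeber time of interest.
#' @return A list with `contingency` (2x2 matrix), `prop_a`, `prop_b`,
#'   `odds_ratio`, `fisher_p`.
#' @export
shift_test <- function(phase_table, group_a, group_b, zt) {
  check_that(length(group_a) > 0 && length(group_b) > 0,
             "both genotype groups must be non-empty")
  pt <- phase_table[phase_table$phase != "excluded", , drop = FALSE]
  a <- pt[pt$genotype %in% group_a, , drop = FALSE]
  b <- pt[pt$genotype %in% group_b, , drop = FALSE]
  check_that(nrow(a) > 0 && nrow(b) > 0,
             "no phased targets in one of the groups")
  tab <- matrix(c(sum(a$phase == zt), sum(a$phase != zt),
                  sum(b$phase == zt), sum(b$phase != zt)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                phase = c(zt, "other")))
  ft <- fisher.test(tab)
  list(contingency = tab,
       prop_a = tab[1, 1] / sum(tab[1, ]),
       prop_b = tab[2, 1] / sum(tab[2, ]),
       odds_ratio = unname(ft$estimate),
       fisher_p = ft$p.value)
}

#' Hypergeometric test for the overlap of two target sets
#'
#' Upper-tail probability of observing at least the realized intersection
#' when both sets are drawn from a common gene universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Number of genes in the universe.
#' @return A list with `overlap`, `expected`, and `p` (upper-tail
#'   hypergeometric).
#' @examples
#' overlap_test(letters[1:10], letters[5:14], universe_size = 100)
#' @export
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  check_that(length(set_a) <= universe_size &&
               length(set_b) <= universe_size,
             "set sizes cannot exceed the universe")
  k <- length(intersect(set_a, set_b))
  check_that(k <= min(length(set_a), length(set_b)),
             "overlap exceeds the smaller set")
  p <- phyper(k - 1, length(set_a), universe_size - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = k,
       expected = length(set_a) * length(set_b) / universe_size,
       p = p)
}

#' Permutation test for a multi-set shared-target overlap
#'
#' Supplements the pairwise hypergeometric tests for the four-genotype
#' shared set: labels are shuffled over the universe (each set replaced by
#' a uniform draw of its own size) and the common intersection size is
#' re-measured; the p-value uses the add-one permutation estimator.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector of all gene ids.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with `observed`, `perm_mean`, and `p`.
#' @export
shared_overlap_permutation <- function(sets, universe, n_perm = 1000L,
                                       seed = 1L) {
  observed <- length(Reduce(intersect, sets))
  sizes <- lengths(sets)
  check_that(all(sizes <= length(universe)),
             "set sizes cannot exceed the universe")
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      length(Reduce(intersect,
                    lapply(sizes, function(n) sample(universe, n))))
    }, numeric(1))
  })
  list(observed = observed, perm_mean = mean(perm),
       p = (1 + sum(perm >= observed)) / (n_perm + 1))
}
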