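#' Build per-gene binding-phase tables for each genotype
#'
#' For every target gene of every genotype, counts treatment and control
#' fragments in the gene's assigned master-peak intervals for each
#' (ZT, replicate), forms pseudocounted treatment/control abundances, and
#' runs [assign_phase()].
#'
#' @param master_sets Named list (per genotype) of master `peak_set`s.
#' @param assignments Named list (per genotype) of [assign_targets()]
#'   outputs against the matching master set.
#' @param samples Named list of deduplicated, depth-normalized
#'   [fragment_set()]s.
#' @param replicates Replicates per (genotype, ZT).
#' @param alpha Significance cutoff passed to [assign_phase()].
#' @param pseudocount Pseudocount for the abundance ratio.
#' @param log Run the phase tests on log2 abundances.
#' @return data.frame with `gene_id`, `genotype`, `anova_p`, `tie_p`,
#'   `phase`, and mean abundances `mean_ZT3`, `mean_ZT9`, `mean_ZT15`.
#' @export
build_phase_tables <- function(master_sets, assignments, samples,
                               replicates = 2L, alpha = 0.05,
                               pseudocount = 1, log = TRUE) {
  rows <- list()
  for (g in names(master_sets)) {
    mp <- master_sets[[g]]
    asg <- assignments[[g]]
    if (nrow(mp) == 0 || nrow(asg) == 0) next
    ir <- IRanges::IRanges(mp$start + 1L, mp$end)
    genes <- sort(unique(asg$gene_id))
    gi <- match(asg$gene_id, genes)

    # per-(zt, rep): fragment counts per master peak, then per gene
    treat <- array(0, c(length(genes), 3, replicates),
                   dimnames = list(genes, ZT_LEVELS, NULL))
    ctrl <- treat
    for (zt_i in seq_along(ZT_LEVELS)) {
      for (r in seq_len(replicates)) {
        for (tr in c("ChIP", "input")) {
          key <- sample_key(g, ZT_LEVELS[zt_i], r, tr)
          if (!key %in% names(samples)) {
            stop("missing sample: ", key, call. = FALSE)
          }
          f <- samples[[key]]$fragments
          cnt <- IRanges::countOverlaps(
            ir, IRanges::IRanges(f$start + 1L, f$end))
          per_gene <- rowsum(cnt[asg$peak], gi)
          tot <- numeric(length(genes))
          tot[as.integer(rownames(per_gene))] <- per_gene[, 1]
          if (tr == "ChIP") treat[, zt_i, r] <- tot
          else ctrl[, zt_i, r] <- tot
        }
      }
    }
    ab <- (treat + pseudocount) / (ctrl + pseudocount)
    zt_col <- rep(ZT_LEVELS, times = replicates)
    anova_p <- tie_p <- numeric(length(genes))
    phase <- character(length(genes))
    for (k in seq_along(genes)) {
      res <- assign_phase(
        quick_df(list(zt = zt_col, abundance = as.vector(ab[k, , ]))),
        alpha = alpha, log = log)
      anova_p[k] <- res$anova_p
      tie_p[k] <- res$tie_p
      phase[k] <- res$phase
    }
    rows[[g]] <- data.frame(
      gene_id = genes, genotype = g, anova_p = anova_p, tie_p = tie_p,
      phase = phase,
      mean_ZT3 = rowMeans(ab[, "ZT3", , drop = FALSE], dims = 1),
      mean_ZT9 = rowMeans(ab[, "ZT9", , drop = FALSE], dims = 1),
      mean_ZT15 = rowMeans(ab[, "ZT15", , drop = FALSE], dims = 1),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truth-defined master intervals for parameter-recovery runs
#'
#' Builds, for each genotype, the promoter intervals of the genes the
#' simulation truth marks as bound, shaped like a master `peak_set` with a
#' matching one-peak-per-gene assignment table. Used to measure phase
#' recovery independently of the peak-calling stage.
#'
#' @param sim A `zb_sim` from [simulate_genome()].
#' @param width Interval width (bp) centered on the planted enrichment bump.
#' @return A list with `master_sets` and `assignments`, both named by
#'   genotype.
#' @export
truth_master_sets <- function(sim, width = 1000L) {
  half <- width %/% 2
  master_sets <- list()
  assignments <- list()
  for (g in GENOTYPES) {
    tg <- sim$truth[sim$truth$genotype == g & sim$truth$bound, , drop = FALSE]
    idx <- match(tg$gene_id, sim$genes$gene_id)
    center <- sim$genes$bump_center[idx]
    mp <- data.frame(
      chrom = "chr1",
      start = pmax(0L, center - half),
      end = pmin(sim$design$genome_length, center + half),
      summit = center, p_value = NA_real_, fold_enrichment = NA_real_,
      genotype = g, zt = NA_character_, stringsAsFactors = FALSE)
    master_sets[[g]] <- peak_set(mp, source = "master")
    assignments[[g]] <- data.frame(gene_id = tg$gene_id,
                                   peak = seq_len(nrow(mp)),
                                   genotype = g, zt = NA_character_,
                                   stringsAsFactors = FALSE)
  }
  list(master_sets = master_sets, assignments = assignments)
}

#' One phase-composition recovery run
#'
#' Generates a truth-only simulation (every gene bound in every genotype,
#' no PCR duplicates), simulates the ChIP/input fragment sets, measures
#' per-gene abundances over the planted promoter intervals, assigns phases,
#' and contrasts the hybrid and inbred groups at one ZT. This isolates the
#' abundance/phase/contrast stages from peak calling, so it measures how
#' well the planted group phase compositions are recovered from fragment
#' data.
#'
#' @param seed Integer seed for the run.
#' @param n_genes Genes per run.
#' @param design Optional [sim_design()] overriding the recovery defaults.
#' @param zt ZT of the contrast.
#' @param alpha Phase-assignment cutoff.
#' @return A list with `prop_hybrid`, `prop_inbred` (recovered ZT
#'   proportions among phased targets), `truth_hybrid`, `truth_inbred`
#'   (planted parameters), `excluded_fraction`, and `fisher_p`.
#' @export
recover_phase_composition <- function(seed, n_genes = 400, design = NULL,
                                      zt = "ZT3", alpha = 0.05) {
  if (is.null(design)) {
    design <- sim_design(n_genes = n_genes, bound_fraction = 1,
                         class_probs = c(shared = 1, hybrid_specific = 0,
                                         inbred_specific = 0),
                         duplicate_rate = 0, seed = seed)
  }
  sim <- simulate_genome(design, with_sequence = FALSE)
  frags <- simulate_chip_fragments(sim)
  tm <- truth_master_sets(sim)
  pt <- build_phase_tables(tm$master_sets, tm$assignments, frags,
                           replicates = design$replicates, alpha = alpha)
  st <- shift_test(pt, HYBRIDS, INBREDS, zt)
  list(prop_hybrid = st$prop_a, prop_inbred = st$prop_b,
       truth_hybrid = unname(design$hybrid_phase_probs[zt]),
       truth_inbred = unname(design$inbred_phase_probs[zt]),
       excluded_fraction = mean(pt$phase == "excluded"),
       fisher_p = st$fisher_p)
}

#' Temporal-shift contrast on truth-level phase draws
#'
#' Draws per-target phase labels directly from the group phase
#' probabilities (no fragment noise) and runs [shift_test()]; used to study
#' the contrast's operating characteristics, e.g. its type-I error when
#' both groups share the same phase distribution.
#'
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream
#'   (the usual choice inside a larger seeded Monte Carlo experiment).
#' @param n_genes Genes (targets per genotype).
#' @param hybrid_phase_probs,inbred_phase_probs Phase distributions over
#'   `(ZT3, ZT9, ZT15)`.
#' @param zt ZT of the contrast.
#' @return The [shift_test()] result.
#' @export
shift_test_simulation <- function(seed = NULL, n_genes = 400,
                                  hybrid_phase_probs = c(0.4, 0.35, 0.25),
                                  inbred_phase_probs = c(0.4, 0.35, 0.25),
                                  zt = "ZT3") {
  run <- function() {
    gid <- sprintf("gene%04d", seq_len(n_genes))
    rows <- lapply(GENOTYPES, function(g) {
      probs <- if (g %in% HYBRIDS) hybrid_phase_probs else inbred_phase_probs
      data.frame(gene_id = gid, genotype = g,
                 phase = sample(ZT_LEVELS, n_genes, TRUE, probs),
                 stringsAsFactors = FALSE)
    })
    shift_test(do.call(rbind, rows), HYBRIDS, INBREDS, zt)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Run the full binding phase-shift pipeline on a simulated experiment
#'
#' Chains every stage: deduplication, down-sampling depth normalization,
#' per-sample Poisson local-background peak calling against the matched
#' input, replicate concordance, per-genotype master peaks, 10-kb target
#' assignment, abundance-based phase assignment, genotype partitioning, and
#' the hybrids-vs-inbreds Fisher temporal-shift contrasts.
#'
#' @param sim A `zb_sim` from [simulate_genome()].
#' @param frags Optional pre-generated fragment list (defaults to
#'   [simulate_chip_fragments()] of `sim`).
#' @param p_cut Peak-calling p-value cutoff.
#' @param alpha Phase-assignment significance cutoff.
#' @param window Target-assignment window (bp).
#' @param seed Seed for the down-sampling draws.
#' @param chip_only Restrict down-sampling normalization to ChIP samples.
#' @return A list with `samples` (normalized), `peaks` (replicate-level),
#'   `concordant`, `master_sets`, `assignments`, `targets` (per-genotype
#'   non-redundant gene sets), `phase_table`, `partition`, `shift` (per-ZT
#'   hybrids-vs-inbreds contrasts), and `shared_overlap` (hypergeometric
#'   test of the H12 x H21 target overlap plus the 4-set permutation
#'   supplement is left to the caller).
#' @export
run_binding_pipeline <- function(sim, frags = NULL, p_cut = 1e-3,
                                 alpha = 0.05, window = 10000L,
                                 seed = sim$design$seed + 2L,
                                 chip_only = FALSE) {
  design <- sim$design
  if (is.null(frags)) frags <- simulate_chip_fragments(sim)
  frags <- lapply(frags, deduplicate)
  frags <- downsample_all(frags, seed = seed, chip_only = chip_only)

  peaks <- list()
  concordant <- list()
  master_sets <- list()
  for (g in GENOTYPES) {
    per_zt <- list()
    for (zt in ZT_LEVELS) {
      reps <- list()
      for (r in seq_len(design$replicates)) {
        treat <- fragment_pileup(frags[[sample_key(g, zt, r, "ChIP")]])
        ctrl <- fragment_pileup(frags[[sample_key(g, zt, r, "input")]])
        reps[[r]] <- call_peaks(treat, ctrl, p_cut = p_cut,
                                genotype = g, zt = zt)
        peaks[[sample_key(g, zt, r, "ChIP")]] <- reps[[r]]
      }
      per_zt[[zt]] <- Reduce(concordant_peaks, reps)
      concordant[[paste(g, zt, sep = "_")]] <- per_zt[[zt]]
    }
    master_sets[[g]] <- master_peaks(per_zt)
  }

  assignments <- lapply(master_sets, assign_targets, genes = sim$genes,
                        window = window)
  targets <- lapply(assignments, function(a) sort(unique(a$gene_id)))
  phase_table <- build_phase_tables(master_sets, assignments, frags,
                                    replicates = design$replicates,
                                    alpha = alpha)
  partition <- partition_targets(targets)
  shift <- lapply(setNames(ZT_LEVELS, ZT_LEVELS), function(zt)
    shift_test(phase_table, HYBRIDS, INBREDS, zt))
  shared_overlap <- overlap_test(targets$H12, targets$H21,
                                 universe_size = nrow(sim$genes))

  list(samples = frags, peaks = peaks, concordant = concordant,
       master_sets = master_sets, assignments = assignments,
       targets = targets, phase_table = phase_table, partition = partition,
       shift = shift, shared_overlap = shared_overlap)
}
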