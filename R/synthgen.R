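#' Simulation design for a diurnal ChIP-seq experiment
#'
#' Collects every tunable parameter of the synthetic-data generator. The
#' default design mirrors the experimental layout the package targets:
#' 4 genotypes (inbreds `P1`, `P2`; reciprocal hybrids `H12`, `H21`) x
#' 3 zeitgeber times (`ZT3`, `ZT9`, `ZT15`) x 2 replicates, each ChIP sample
#' with a matched input, paired-end fragments of mean length 400 bp.
#'
#' Binding phases are drawn per gene and genotype from
#' `hybrid_phase_probs` / `inbred_phase_probs` over `(ZT3, ZT9, ZT15)`;
#' the defaults plant the morning-shifted hybrid composition used throughout
#' the package's recovery tests. Occupancy is expressed as fold enrichment
#' over local background: `enrichment` at the planted phase,
#' `off_phase_occupancy` elsewhere (flat genes carry `enrichment` at all
#' three ZTs and no planted phase).
#'
#' @param n_genes Number of gene models to plant.
#' @param genome_length Genome size in bp; `NULL` sizes the genome
#'   automatically to `n_genes * (gene span + 20 kb)`.
#' @param fragment_length_mean,fragment_length_sd Fragment length model (bp).
#' @param depth_per_sample Fragments per sample before PCR duplication.
#' @param duplicate_rate Fraction of emitted fragments that are exact PCR
#'   copies, in `[0, 1)`.
#' @param replicates Biological replicates per (genotype, ZT).
#' @param hybrid_phase_probs,inbred_phase_probs Length-3 probability vectors
#'   over `(ZT3, ZT9, ZT15)` for the binding phase of bound genes.
#' @param motif_plant_rate Fraction of gene promoters carrying the planted
#'   consensus motif.
#' @param motif Name of the consensus to plant (a row of [known_motifs()]),
#'   or a single A/C/G/T string.
#' @param bound_fraction Fraction of genes bound in at least one genotype.
#' @param class_probs Probabilities that a bound gene is shared by all four
#'   genotypes, hybrid-specific, or inbred-specific.
#' @param flat_fraction Fraction of bound genes with flat (phase-less)
#'   occupancy across ZTs.
#' @param enrichment Fold enrichment over background at the planted phase.
#' @param off_phase_occupancy Fold enrichment at non-planted phases (1 =
#'   background level).
#' @param bump_sd Standard deviation (bp) of the Gaussian enrichment bump of
#'   fragment centers around the bound promoter.
#' @param utr5_length,cds_length Gene geometry (bp); the promoter used for
#'   motif planting and feature classification is 2 kb upstream of the TSS.
#' @param go_n_terms,go_base_rate,go_focal_term,go_focal_enrichment GO-label
#'   model: number of background terms, per-gene term probability, id of the
#'   focal term, and its enrichment factor among bound genes.
#' @param expr_mode_probs Probabilities that a gene is additive,
#'   nonadditive-up, or nonadditive-down in the expression simulator.
#' @param seed Default integer seed used by the generators.
#'
#' @return An object of class `sim_design` (a validated list).
#' @seealso [simulate_genome()], [simulate_chip_fragments()]
#' @examples
#' d <- sim_design(n_genes = 20, depth_per_sample = 2000)
#' d$genome_length
#' @export
sim_design <- function(n_genes = 300,
                       genome_length = NULL,
                       fragment_length_mean = 400,
                       fragment_length_sd = 50,
                       depth_per_sample = 200000,
                       duplicate_rate = 0.1,
                       replicates = 2,
                       hybrid_phase_probs = c(0.65, 0.20, 0.15),
                       inbred_phase_probs = c(0.40, 0.35, 0.25),
                       motif_plant_rate = 0.8,
                       motif = "EE",
                       bound_fraction = 0.5,
                       class_probs = c(shared = 0.7, hybrid_specific = 0.15,
                                       inbred_specific = 0.15),
                       flat_fraction = 0,
                       enrichment = 10,
                       off_phase_occupancy = 1,
                       bump_sd = 200,
                       utr5_length = 200,
                       cds_length = 2500,
                       go_n_terms = 15,
                       go_base_rate = 0.05,
                       go_focal_term = "GO:0015979",
                       go_focal_enrichment = 10,
                       expr_mode_probs = c(additive = 0.8,
                                           `nonadditive-up` = 0.1,
                                           `nonadditive-down` = 0.1),
                       seed = 1L) {
  check_that(is.numeric(n_genes) && n_genes >= 0, "'n_genes' must be >= 0")
  check_rate(duplicate_rate, "duplicate_rate")
  check_that(duplicate_rate < 1, "'duplicate_rate' must be < 1")
  check_rate(motif_plant_rate, "motif_plant_rate")
  check_rate(bound_fraction, "bound_fraction")
  check_rate(flat_fraction, "flat_fraction")
  check_rate(go_base_rate, "go_base_rate")
  check_that(replicates >= 1, "'replicates' must be >= 1")
  check_that(enrichment >= 1, "'enrichment' must be >= 1")
  check_that(off_phase_occupancy >= 0, "'off_phase_occupancy' must be >= 0")
  for (p in list(hybrid_phase_probs, inbred_phase_probs)) {
    check_that(length(p) == 3 && all(p >= 0) && abs(sum(p) - 1) < 1e-9,
               "phase-probability vectors must have length 3 and sum to 1")
  }
  check_that(abs(sum(class_probs) - 1) < 1e-9 && all(class_probs >= 0),
             "'class_probs' must be non-negative and sum to 1")
  check_that(abs(sum(expr_mode_probs) - 1) < 1e-9,
             "'expr_mode_probs' must sum to 1")

  gene_span <- utr5_length + cds_length
  slot <- gene_span + 20000L
  min_len <- n_genes * slot
  if (is.null(genome_length)) genome_length <- max(min_len, 50000L)
  if (genome_length < min_len) {
    stop(sprintf(
      "genome_length %d too small for %d genes: need >= %d (deficit %d bp)",
      genome_length, n_genes, min_len, min_len - genome_length), call. = FALSE)
  }

  if (motif %in% known_motifs()$name) {
    motif_consensus <- known_motifs()$consensus[known_motifs()$name == motif]
  } else {
    check_that(grepl("^[ACGT]+$", motif),
               "'motif' must name a known motif or be an A/C/G/T string")
    motif_consensus <- motif
  }

  structure(list(
    n_genes = as.integer(n_genes),
    genome_length = as.integer(genome_length),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    depth_per_sample = as.integer(depth_per_sample),
    duplicate_rate = duplicate_rate,
    replicates = as.integer(replicates),
    hybrid_phase_probs = setNames(hybrid_phase_probs, ZT_LEVELS),
    inbred_phase_probs = setNames(inbred_phase_probs, ZT_LEVELS),
    motif_plant_rate = motif_plant_rate,
    motif_name = if (motif %in% known_motifs()$name) motif else "custom",
    motif_consensus = motif_consensus,
    bound_fraction = bound_fraction,
    class_probs = class_probs,
    flat_fraction = flat_fraction,
    enrichment = enrichment,
    off_phase_occupancy = off_phase_occupancy,
    bump_sd = bump_sd,
    utr5_length = as.integer(utr5_length),
    cds_length = as.integer(cds_length),
    gene_span = as.integer(gene_span),
    slot = as.integer(slot),
    go_n_terms = as.integer(go_n_terms),
    go_base_rate = go_base_rate,
    go_focal_term = go_focal_term,
    go_focal_enrichment = go_focal_enrichment,
    expr_mode_probs = expr_mode_probs,
    seed = as.integer(seed)
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "sim_design: %d genes over %s bp; depth %d fragments/sample; %d replicates\n",
    x$n_genes, format(x$genome_length, big.mark = ","),
    x$depth_per_sample, x$replicates))
  cat(sprintf("  hybrid phase probs  (ZT3,ZT9,ZT15): %s\n",
              paste(x$hybrid_phase_probs, collapse = ", ")))
  cat(sprintf("  inbred phase probs  (ZT3,ZT9,ZT15): %s\n",
              paste(x$inbred_phase_probs, collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic genome, gene annotation, and planted truth
#'
#' Builds a uniform-random single-chromosome genome, lays out
#' `design$n_genes` non-overlapping gene models (TSS, 5'UTR, CDS, random
#' strand) on a 20-kb spacing grid, plants the design's consensus motif in a
#' `motif_plant_rate` fraction of 2-kb promoters (random strand), assigns GO
#' labels, and draws the per-genotype binding truth (bound status, binding
#' class, planted phase, per-ZT occupancy).
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; defaults to `design$seed`.
#' @param with_sequence Generate the nucleotide sequence (default). Set
#'   `FALSE` for truth-only simulations (e.g. phase-recovery runs) that
#'   never touch the sequence: the `genome` element is then empty and no
#'   motifs are physically planted.
#' @return A list of class `zb_sim` with elements `genome`
#'   (a [Biostrings::DNAStringSet] with one sequence, `chr1`), `genes`
#'   (data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `tes`,
#'   `utr5_start`, `utr5_end`, `cds_start`, `cds_end`, `bump_center`,
#'   `motif_planted`, `expression_mode`; 0-based half-open intervals),
#'   `truth` (data.frame: `gene_id`, `genotype`, `bound`, `flat`,
#'   `planted_phase`, `occ_ZT3`, `occ_ZT9`, `occ_ZT15`), `go` (data.frame:
#'   `gene_id`, `term_id`), and `design`.
#' @examples
#' sim <- simulate_genome(sim_design(n_genes = 5, seed = 7))
#' sim$genes$gene_id
#' @export
simulate_genome <- function(design, seed = design$seed,
                            with_sequence = TRUE) {
  stopifnot(inherits(design, "sim_design"))
  withr::with_seed(seed, simulate_genome_impl(design, with_sequence))
}

simulate_genome_impl <- function(design, with_sequence = TRUE) {
  n <- design$n_genes
  L <- design$genome_length
  bases <- c("A", "C", "G", "T")
  genome_chars <- if (with_sequence) sample(bases, L, replace = TRUE)
                  else character(0)

  if (n == 0L) {
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chr1"
    return(structure(list(
      genome = genome,
      genes = empty_gene_table(),
      truth = empty_truth_table(),
      go = data.frame(gene_id = character(), term_id = character()),
      design = design), class = "zb_sim"))
  }

  span <- design$gene_span
  slot <- design$slot
  # one gene per 20-kb slot, jittered, so promoters and 10-kb windows of
  # neighbouring genes cannot collide with the gene body grid
  jitter <- sample(6000:14000, n, replace = TRUE)
  start <- (seq_len(n) - 1L) * slot + jitter
  end <- start + span
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1L)
  tes <- ifelse(strand == "+", end - 1L, start)
  u5 <- design$utr5_length
  utr5_start <- ifelse(strand == "+", start, end - u5)
  utr5_end <- ifelse(strand == "+", start + u5, end)
  cds_start <- ifelse(strand == "+", start + u5, start)
  cds_end <- ifelse(strand == "+", end, end - u5)

  prom <- promoter_interval(tss, strand, width = 2000L, genome_length = L)
  bump_center <- as.integer((prom$start + prom$end) %/% 2)

  gene_id <- sprintf("gene%04d", seq_len(n))
  motif_planted <- runif(n) < design$motif_plant_rate
  if (with_sequence) {
    consensus <- design$motif_consensus
    mlen <- nchar(consensus)
    rc <- revcomp_string(consensus)
    for (i in which(motif_planted)) {
      pos <- sample.int(prom$end[i] - prom$start[i] - mlen + 1L, 1L) +
        prom$start[i] - 1L  # 0-based insert position
      word <- if (runif(1) < 0.5) consensus else rc
      genome_chars[(pos + 1L):(pos + mlen)] <- strsplit(word, "")[[1]]
    }
  }

  expression_mode <- sample(names(design$expr_mode_probs), n, replace = TRUE,
                            prob = design$expr_mode_probs)

  genes <- data.frame(
    gene_id = gene_id, chrom = "chr1", strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(tss), tes = as.integer(tes),
    utr5_start = as.integer(utr5_start), utr5_end = as.integer(utr5_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    bump_center = bump_center,
    motif_planted = motif_planted,
    expression_mode = expression_mode,
    stringsAsFactors = FALSE
  )

  truth <- draw_binding_truth(gene_id, design)
  go <- draw_go_labels(gene_id, truth, design)

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chr1"
  structure(list(genome = genome, genes = genes, truth = truth, go = go,
                 design = design), class = "zb_sim")
}

#' @export
print.zb_sim <- function(x, ...) {
  n_bound <- if (nrow(x$truth) > 0)
    sum(tapply(x$truth$bound, x$truth$gene_id, any)) else 0L
  cat(sprintf(
    "zb_sim: %d genes on a %s-bp genome; %d bound in >=1 genotype\n",
    nrow(x$genes), format(x$design$genome_length, big.mark = ","), n_bound))
  invisible(x)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), tss = integer(),
             tes = integer(), utr5_start = integer(), utr5_end = integer(),
             cds_start = integer(), cds_end = integer(),
             bump_center = integer(), motif_planted = logical(),
             expression_mode = character(), stringsAsFactors = FALSE)
}

empty_truth_table <- function() {
  data.frame(gene_id = character(), genotype = character(), bound = logical(),
             flat = logical(), planted_phase = character(),
             occ_ZT3 = numeric(), occ_ZT9 = numeric(), occ_ZT15 = numeric(),
             stringsAsFactors = FALSE)
}

# promoter as 0-based half-open interval upstream of the TSS, strand-aware
promoter_interval <- function(tss, strand, width = 2000L, genome_length) {
  start <- ifelse(strand == "+", tss - width, tss + 1L)
  end <- ifelse(strand == "+", tss, tss + 1L + width)
  data.frame(start = pmax(0L, as.integer(start)),
             end = pmin(as.integer(genome_length), as.integer(end)))
}

#' Promoter intervals of simulated genes as a peak-style table
#'
#' Convenience accessor for motif-recovery analyses: the strand-aware
#' promoter window of every simulated gene, shaped like a peak table.
#'
#' @param sim A `zb_sim`.
#' @param width Promoter width in bp.
#' @return data.frame with `chrom`, `start`, `end`, `summit`.
#' @export
promoter_peaks <- function(sim, width = 2000L) {
  prom <- promoter_interval(sim$genes$tss, sim$genes$strand, width,
                            sim$design$genome_length)
  data.frame(chrom = sim$genes$chrom, start = prom$start, end = prom$end,
             summit = as.integer((prom$start + prom$end) %/% 2),
             stringsAsFactors = FALSE)
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

draw_binding_truth <- function(gene_id, design) {
  n <- length(gene_id)
  bound_gene <- runif(n) < design$bound_fraction
  class <- rep("unbound", n)
  class[bound_gene] <- sample(names(design$class_probs), sum(bound_gene),
                              replace = TRUE, prob = design$class_probs)
  flat_gene <- bound_gene & runif(n) < design$flat_fraction

  rows <- vector("list", length(GENOTYPES))
  for (gi in seq_along(GENOTYPES)) {
    g <- GENOTYPES[gi]
    is_hybrid <- g %in% HYBRIDS
    bound_here <- bound_gene & (class == "shared" |
      (is_hybrid & class == "hybrid_specific") |
      (!is_hybrid & class == "inbred_specific"))
    probs <- if (is_hybrid) design$hybrid_phase_probs else design$inbred_phase_probs
    phase <- rep(NA_character_, n)
    k <- bound_here & !flat_gene
    phase[k] <- sample(ZT_LEVELS, sum(k), replace = TRUE, prob = probs)
    occ <- matrix(0, n, 3, dimnames = list(NULL, ZT_LEVELS))
    occ[bound_here, ] <- design$off_phase_occupancy
    occ[flat_gene & bound_here, ] <- design$enrichment
    for (z in ZT_LEVELS) occ[which(phase == z), z] <- design$enrichment
    rows[[gi]] <- data.frame(
      gene_id = gene_id, genotype = g, bound = bound_here,
      flat = flat_gene & bound_here, planted_phase = phase,
      occ_ZT3 = occ[, "ZT3"], occ_ZT9 = occ[, "ZT9"], occ_ZT15 = occ[, "ZT15"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

draw_go_labels <- function(gene_id, truth, design) {
  terms <- sprintf("GO:%07d", seq_len(design$go_n_terms))
  bound_any <- tapply(truth$bound, truth$gene_id, any)[gene_id]
  out <- list()
  for (t in terms) {
    hit <- runif(length(gene_id)) < design$go_base_rate
    if (any(hit)) out[[t]] <- data.frame(gene_id = gene_id[hit], term_id = t,
                                         stringsAsFactors = FALSE)
  }
  p_focal <- ifelse(bound_any,
                    pmin(1, design$go_base_rate * design$go_focal_enrichment),
                    design$go_base_rate)
  hit <- runif(length(gene_id)) < p_focal
  if (any(hit)) {
    out[[design$go_focal_term]] <- data.frame(
      gene_id = gene_id[hit], term_id = design$go_focal_term,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), term_id = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$term_id), , drop = FALSE]
}

#' Generate ChIP and input fragment sets for every sample
#'
#' For each (genotype, ZT, replicate) the generator emits one ChIP and one
#' input [fragment_set()]. Input samples contain only uniform background
#' fragments. ChIP samples additionally place fragments whose centers follow
#' a Gaussian bump (sd `design$bump_sd`) over the promoter of each bound
#' gene, with the extra fragment count chosen so that the expected summit
#' coverage equals `occupancy x background coverage` at that ZT. A
#' `duplicate_rate` fraction of each emitted set are exact PCR copies.
#'
#' @param sim A `zb_sim` from [simulate_genome()].
#' @param design Defaults to `sim$design`.
#' @param seed Integer seed; defaults to `design$seed + 1`.
#' @return A named list of [fragment_set()] objects
#'   (`"<genotype>_<ZT>_rep<k>_<ChIP|input>"`).
#' @examples
#' sim <- simulate_genome(sim_design(n_genes = 4, depth_per_sample = 500))
#' frags <- simulate_chip_fragments(sim)
#' names(frags)[1:4]
#' @export
simulate_chip_fragments <- function(sim, design = sim$design,
                                    seed = design$seed + 1L) {
  stopifnot(inherits(sim, "zb_sim"))
  bad <- sim$truth$bound &
    (sim$truth$occ_ZT3 + sim$truth$occ_ZT9 + sim$truth$occ_ZT15) == 0
  if (any(bad)) {
    stop("truth inconsistency: bound gene(s) with all-zero occupancy: ",
         paste(unique(sim$truth$gene_id[bad]), collapse = ", "), call. = FALSE)
  }
  withr::with_seed(seed, simulate_chip_fragments_impl(sim, design))
}

simulate_chip_fragments_impl <- function(sim, design) {
  L <- design$genome_length
  depth <- design$depth_per_sample
  mu <- design$fragment_length_mean
  c0 <- depth * mu / L  # expected background coverage per base
  p_cov <- 2 * pnorm(mu / 2 / design$bump_sd) - 1

  centers <- setNames(sim$genes$bump_center, sim$genes$gene_id)
  out <- list()
  for (g in GENOTYPES) {
    tg <- sim$truth[sim$truth$genotype == g & sim$truth$bound, , drop = FALSE]
    for (zt in ZT_LEVELS) {
      occ <- tg[[paste0("occ_", zt)]]
      lam <- pmax(0, (occ - 1)) * c0 / p_cov
      for (rep_i in seq_len(design$replicates)) {
        n_sig <- rpois(length(lam), lam)
        frag_sig <- signal_fragments(centers[tg$gene_id], n_sig, design)
        n_bg <- max(0L, depth - sum(n_sig))
        bg_f <- background_fragments(n_bg, design)
        chip <- quick_df(list(chrom = c(bg_f$chrom, frag_sig$chrom),
                              start = c(bg_f$start, frag_sig$start),
                              end = c(bg_f$end, frag_sig$end),
                              strand = c(bg_f$strand, frag_sig$strand)))
        out[[sample_key(g, zt, rep_i, "ChIP")]] <- fragment_set(
          sample_id = sample_key(g, zt, rep_i, "ChIP"),
          genotype = g, zt = zt, replicate = rep_i, treatment = "ChIP",
          fragments = add_duplicates(chip, design$duplicate_rate),
          genome_length = L)
        out[[sample_key(g, zt, rep_i, "input")]] <- fragment_set(
          sample_id = sample_key(g, zt, rep_i, "input"),
          genotype = g, zt = zt, replicate = rep_i, treatment = "input",
          fragments = add_duplicates(background_fragments(depth, design),
                                     design$duplicate_rate),
          genome_length = L)
      }
    }
  }
  out
}

sample_key <- function(genotype, zt, replicate, treatment) {
  sprintf("%s_%s_rep%d_%s", genotype, zt, replicate, treatment)
}

frag_lengths <- function(n, design) {
  pmax.int(50L, as.integer(round(rnorm(n, design$fragment_length_mean,
                                       design$fragment_length_sd))))
}

# data.frame without the validation/copy overhead, for bulk fragment tables
quick_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

background_fragments <- function(n, design) {
  if (n == 0L) return(empty_fragment_table())
  len <- frag_lengths(n, design)
  start <- as.integer(floor(runif(n, 0, design$genome_length - len)))
  quick_df(list(chrom = rep.int("chr1", n), start = start, end = start + len,
                strand = sample(c("+", "-"), n, replace = TRUE)))
}

signal_fragments <- function(center, n_per_gene, design) {
  total <- sum(n_per_gene)
  if (total == 0L) return(empty_fragment_table())
  mid <- rep(center, n_per_gene) + rnorm(total, 0, design$bump_sd)
  len <- frag_lengths(total, design)
  start <- as.integer(round(mid - len / 2))
  start <- pmax.int(0L, pmin.int(start, design$genome_length - len))
  quick_df(list(chrom = rep.int("chr1", total), start = start,
                end = start + len,
                strand = sample(c("+", "-"), total, replace = TRUE)))
}

add_duplicates <- function(frags, duplicate_rate) {
  if (duplicate_rate <= 0 || nrow(frags) == 0L) return(frags)
  n_dup <- round(nrow(frags) * duplicate_rate / (1 - duplicate_rate))
  if (n_dup == 0L) return(frags)
  dup_idx <- sample.int(nrow(frags), n_dup, replace = TRUE)
  order_idx <- sample.int(nrow(frags) + n_dup)
  quick_df(lapply(frags, function(col) c(col, col[dup_idx])[order_idx]))
}
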