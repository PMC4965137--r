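test_that("motif planting at rate 1 puts the consensus in every promoter", {
  d <- sim_design(n_genes = 10, motif_plant_rate = 1, motif = "EE",
                  depth_per_sample = 100, seed = 42)
  sim <- simulate_genome(d)
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(10)) {
    gene <- sim$genes[i, ]
    if (gene$strand == "+") {
      prom <- substr(g, gene$tss - 2000 + 1, gene$tss)
    } else {
      prom <- substr(g, gene$tss + 2, gene$tss + 1 + 2000)
    }
    expect_true(grepl("AAATATCT", prom) || grepl("AGATATTT", prom),
                info = gene$gene_id)
  }
})

test_that("zero genes give an empty annotation and truth", {
  sim <- simulate_genome(sim_design(n_genes = 0, genome_length = 60000,
                                    depth_per_sample = 100))
  expect_equal(nrow(sim$genes), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("seeded generation is fully reproducible, down to written files", {
  d <- sim_design(n_genes = 6, depth_per_sample = 500, seed = 7)
  s1 <- simulate_genome(d)
  s2 <- simulate_genome(d)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  f1 <- simulate_chip_fragments(s1)
  f2 <- simulate_chip_fragments(s2)
  expect_identical(f1[[1]]$fragments, f2[[1]]$fragments)

  dir1 <- tempfile(); dir2 <- tempfile()
  write_sim(s1, f1[1], dir1)
  write_sim(s2, f2[1], dir2)
  for (f in c("genome.fa", "genes.gff3")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("an undersized genome is rejected with the deficit", {
  expect_error(sim_design(n_genes = 10, genome_length = 1000),
               "deficit")
})

test_that("planted truth is internally consistent", {
  d <- sim_design(n_genes = 400, flat_fraction = 0.05,
                  depth_per_sample = 100, seed = 9)
  sim <- simulate_genome(d, with_sequence = FALSE)
  tr <- sim$truth
  occ <- as.matrix(tr[c("occ_ZT3", "occ_ZT9", "occ_ZT15")])
  nonflat <- tr$bound & !tr$flat
  # argmax occupancy equals the planted phase for every non-flat bound gene
  expect_true(all(c("ZT3", "ZT9", "ZT15")[max.col(occ[nonflat, ],
                                                  ties.method = "first")]
                  == tr$planted_phase[nonflat]))
  # strict maximum at the planted phase
  top <- apply(occ[nonflat, ], 1, max)
  runner <- apply(occ[nonflat, ], 1, function(x) sort(x, decreasing = TRUE)[2])
  expect_true(all(top > runner))
  # flat genes: equal occupancy, no phase
  expect_true(all(is.na(tr$planted_phase[tr$flat])))
  # genes do not overlap
  g <- sim$genes
  expect_true(all(head(g$end, -1) < tail(g$start, -1)))
})

test_that("group-level phase composition matches the design probabilities", {
  d <- sim_design(n_genes = 400, bound_fraction = 1,
                  class_probs = c(shared = 1, hybrid_specific = 0,
                                  inbred_specific = 0),
                  depth_per_sample = 100, seed = 5)
  sim <- simulate_genome(d, with_sequence = FALSE)
  for (grp in list(list(g = c("H12", "H21"), p = d$hybrid_phase_probs),
                   list(g = c("P1", "P2"), p = d$inbred_phase_probs))) {
    tr <- sim$truth[sim$truth$genotype %in% grp$g, ]
    n <- nrow(tr)
    for (z in c("ZT3", "ZT9", "ZT15")) {
      k <- sum(tr$planted_phase == z)
      lo <- qbinom(0.005, n, grp$p[z]); hi <- qbinom(0.995, n, grp$p[z])
      expect_true(k >= lo && k <= hi,
                  info = sprintf("%s %s: %d not in [%d,%d]",
                                 grp$g[1], z, k, lo, hi))
    }
  }
})

test_that("sample totals and PCR duplication behave as configured", {
  d <- sim_design(n_genes = 5, depth_per_sample = 4000,
                  duplicate_rate = 0.2, seed = 3)
  sim <- simulate_genome(d, with_sequence = FALSE)
  frags <- simulate_chip_fragments(sim)
  expect_length(frags, 4 * 3 * 2 * 2)  # genotypes x ZTs x reps x treatments
  for (fs in frags[1:6]) {
    emitted <- n_fragments(fs)
    unique_n <- n_fragments(deduplicate(fs))
    # emitted = depth / (1 - duplicate_rate); unique close to depth
    expect_equal(emitted, round(4000 / 0.8), tolerance = 0.02)
    expect_gte(unique_n, 0.98 * 4000)
    expect_lte(unique_n, 4000)
  }
  # duplicate_rate = 0: deduplication leaves samples essentially unchanged
  d0 <- sim_design(n_genes = 5, depth_per_sample = 4000,
                   duplicate_rate = 0, seed = 3)
  sim0 <- simulate_genome(d0, with_sequence = FALSE)
  fs0 <- simulate_chip_fragments(sim0)[[1]]
  expect_equal(n_fragments(deduplicate(fs0)), n_fragments(fs0))
})

test_that("a bound gene with zero occupancy is a truth inconsistency", {
  d <- sim_design(n_genes = 2, depth_per_sample = 100, bound_fraction = 1,
                  seed = 1)
  sim <- simulate_genome(d, with_sequence = FALSE)
  sim$truth[1, c("occ_ZT3", "occ_ZT9", "occ_ZT15")] <- 0
  expect_error(simulate_chip_fragments(sim), "inconsistency")
})

test_that("without binding, ChIP and input coverage are exchangeable", {
  ok <- 0L
  for (s in 1:20) {
    d <- sim_design(n_genes = 4, bound_fraction = 0, genome_length = 100000,
                    depth_per_sample = 2000, duplicate_rate = 0, seed = s)
    sim <- simulate_genome(d, with_sequence = FALSE)
    frags <- simulate_chip_fragments(sim)
    chip <- bin_coverage(frags[["P1_ZT3_rep1_ChIP"]], 1000)$values
    inp <- bin_coverage(frags[["P1_ZT3_rep1_input"]], 1000)$values
    p <- suppressWarnings(ks.test(chip, inp)$p.value)
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("a planted high-occupancy site dominates the local pileup", {
  d <- sim_design(n_genes = 2, genome_length = 120000, bound_fraction = 1,
                  class_probs = c(shared = 1, hybrid_specific = 0,
                                  inbred_specific = 0),
                  enrichment = 5, depth_per_sample = 50000,
                  duplicate_rate = 0, seed = 8)
  sim <- simulate_genome(d, with_sequence = FALSE)
  frags <- simulate_chip_fragments(sim)
  tr <- sim$truth
  g <- tr$genotype[tr$bound][1]
  z <- tr$planted_phase[tr$bound & tr$genotype == g][1]
  fs <- frags[[paste0(g, "_", z, "_rep1_ChIP")]]
  pv <- fragment_pileup(fs)$values
  gene <- sim$genes[sim$genes$gene_id ==
                      tr$gene_id[tr$bound & tr$genotype == g &
                                   tr$planted_phase == z][1], ]
  prom_max <- max(pv[(gene$bump_center - 500):(gene$bump_center + 500)])
  expect_gt(prom_max, 3 * median(pv))
})
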