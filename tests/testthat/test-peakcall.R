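test_that("pileup counts covering fragments per base", {
  fs <- make_fs(start = 10, end = 20, genome_length = 30)
  v <- fragment_pileup(fs)$values
  expect_equal(v, c(rep(0, 10), rep(1, 10), rep(0, 10)))

  fs2 <- make_fs(start = c(10, 12), end = c(20, 16), genome_length = 30)
  v2 <- fragment_pileup(fs2)$values
  expect_equal(v2[13:16], rep(2, 4))

  set.seed(7)
  start <- sample.int(800, 60)
  len <- sample(20:100, 60, TRUE)
  fs3 <- make_fs(start = start, end = start + len, genome_length = 1000)
  v3 <- fragment_pileup(fs3)$values
  expect_equal(sum(v3), sum(len))
  expect_equal(v3, brute_pileup(fs3$fragments, 1000), ignore_attr = TRUE)
})

test_that("per-position Poisson p-values match direct series summation", {
  # single-position check at the textbook example k = 20, lambda = 2
  expect_equal(ppois(19, 2, lower.tail = FALSE), poisson_upper_tail(20, 2),
               tolerance = 1e-14)

  set.seed(8)
  L <- 5000
  s1 <- sample.int(L - 300, 400); s2 <- sample.int(L - 300, 500)
  treat <- fragment_pileup(make_fs(s1, s1 + 200, genome_length = L))
  ctrl <- fragment_pileup(make_fs(s2, s2 + 200, genome_length = L))
  ep <- enrichment_pvalues(treat, ctrl)
  idx <- sample.int(L, 200)
  oracle <- mapply(poisson_upper_tail, treat$values[idx], ep$lambda[idx])
  expect_lt(max(abs(ep$p[idx] - oracle)), 1e-10)
})

test_that("local lambda uses the max rule over background windows", {
  L <- 30000
  bg <- numeric(L)
  bg[14500:15500] <- 4  # a concentrated control bump
  ctrl <- coverage_track("chr1", 1L, bg)
  treat <- coverage_track("chr1", 1L, numeric(L))
  lam <- enrichment_pvalues(treat, ctrl)$lambda
  # at the bump center the 1-kb window mean dominates
  expect_equal(lam[15000], mean(bg[14500:15500]), tolerance = 0.01)
  # far away the genome-wide mean is the floor
  expect_equal(lam[1000], mean(bg))
  expect_true(all(lam >= mean(bg)))
})

test_that("peak calling recovers a planted site and respects p_cut", {
  d <- sim_design(n_genes = 2, genome_length = 120000, bound_fraction = 1,
                  class_probs = c(shared = 1, hybrid_specific = 0,
                                  inbred_specific = 0),
                  enrichment = 8, depth_per_sample = 3000,
                  duplicate_rate = 0, seed = 13)
  sim <- simulate_genome(d, with_sequence = FALSE)
  frags <- simulate_chip_fragments(sim)
  tr <- sim$truth[sim$truth$genotype == "P1", ]
  z <- tr$planted_phase[1]
  treat <- fragment_pileup(frags[[paste0("P1_", z, "_rep1_ChIP")]])
  ctrl <- fragment_pileup(frags[[paste0("P1_", z, "_rep1_input")]])
  pk <- call_peaks(treat, ctrl, genotype = "P1", zt = z)
  expect_gt(nrow(pk), 0)
  center <- sim$genes$bump_center[sim$genes$gene_id == tr$gene_id[1]]
  expect_true(any(pk$start <= center & pk$end > center))

  # peak invariants
  expect_true(all(pk$start < pk$end))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  expect_true(all(pk$p_value > 0 & pk$p_value <= 1))
  expect_true(all(pk$fold_enrichment > 0))
  # summit pileup is maximal within the peak
  for (i in seq_len(nrow(pk))) {
    expect_gte(treat$values[pk$summit[i] + 1],
               max(treat$values[pk$start[i] + 1], treat$values[pk$end[i]]))
  }

  # monotonicity: every stricter-cutoff peak lies inside a looser-cutoff peak
  pk_strict <- call_peaks(treat, ctrl, p_cut = 1e-6)
  for (i in seq_len(nrow(pk_strict))) {
    expect_true(any(pk$start <= pk_strict$start[i] &
                      pk$end >= pk_strict$end[i]))
  }
})

test_that("an all-zero control falls back to treatment background", {
  L <- 20000
  set.seed(3)
  s <- sample.int(L - 100, 300)
  treat <- fragment_pileup(make_fs(s, s + 100, genome_length = L))
  ctrl <- coverage_track("chr1", 1L, numeric(L))
  expect_warning(pk <- call_peaks(treat, ctrl), "all-zero")
  expect_s3_class(pk, "peak_set")
})

test_that("replicate concordance keeps union spans of overlapping peaks", {
  mkpk <- function(start, end, p = 1e-5) {
    zeitbind:::peak_set(data.frame(
      chrom = "chr1", start = start, end = end,
      summit = as.integer((start + end) / 2), p_value = p,
      fold_enrichment = 5, genotype = "P1", zt = "ZT3",
      stringsAsFactors = FALSE), source = "replicate-level")
  }
  r1 <- mkpk(100, 200)
  r2 <- mkpk(150, 250)
  out <- concordant_peaks(r1, r2)
  expect_equal(out$start, 100)
  expect_equal(out$end, 250)
  expect_equal(peak_source(out), "concordant")

  # disjoint peaks are dropped
  expect_equal(nrow(concordant_peaks(mkpk(100, 200), mkpk(300, 400))), 0)

  # identical sets pass through with the same coordinates
  same <- mkpk(c(100, 500), c(200, 700))
  out2 <- concordant_peaks(same, same)
  expect_equal(out2$start, c(100, 500))
  expect_equal(out2$end, c(200, 700))

  # membership symmetry: swapping replicates yields the same merged spans
  a <- mkpk(c(100, 400, 900), c(250, 600, 1000))
  b <- mkpk(c(200, 550), c(300, 650))
  ab <- concordant_peaks(a, b)
  ba <- concordant_peaks(b, a)
  expect_equal(ab[c("start", "end")], ba[c("start", "end")])
})

test_that("master peaks are the ZT union with contributing-ZT tags", {
  mkpk <- function(start, end, zt) {
    zeitbind:::peak_set(data.frame(
      chrom = "chr1", start = start, end = end,
      summit = as.integer((start + end) / 2), p_value = 1e-5,
      fold_enrichment = 5, genotype = "P1", zt = zt,
      stringsAsFactors = FALSE), source = "concordant")
  }
  m <- master_peaks(list(ZT3 = mkpk(100, 300, "ZT3"),
                         ZT9 = mkpk(250, 400, "ZT9"),
                         ZT15 = mkpk(1000, 1100, "ZT15")))
  expect_equal(m$start, c(100, 1000))
  expect_equal(m$end, c(400, 1100))
  expect_equal(m$zts, c("ZT3,ZT9", "ZT15"))
  expect_equal(peak_source(m), "master")

  # triple overlap collapses to one interval tagged with all three
  m2 <- master_peaks(list(ZT3 = mkpk(100, 300, "ZT3"),
                          ZT9 = mkpk(200, 400, "ZT9"),
                          ZT15 = mkpk(350, 500, "ZT15")))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$zts, "ZT3,ZT9,ZT15")

  # master peaks are sorted and non-overlapping
  expect_true(all(head(m$end, -1) <= tail(m$start, -1)))
})

test_that("input subtraction is a floored pointwise difference", {
  t1 <- coverage_track("chr1", 1L, c(3, 5, 2, 0, 7))
  expect_equal(input_subtracted_track(t1, t1)$values, rep(0, 5))
  t2 <- coverage_track("chr1", 1L, c(1, 2, 0, 0, 3))
  expect_equal(input_subtracted_track(t1, t2)$values, c(2, 3, 2, 0, 4))
  set.seed(9)
  a <- coverage_track("chr1", 1L, rpois(100, 5))
  b <- coverage_track("chr1", 1L, rpois(100, 5))
  expect_equal(input_subtracted_track(a, b)$values,
               pmax(a$values - b$values, 0))
})
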