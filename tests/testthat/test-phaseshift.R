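test_that("target abundance is the pseudocounted treat/control ratio", {
  # 40 treatment and 10 control fragments inside the master interval
  samples <- list()
  for (zt in c("ZT3", "ZT9", "ZT15")) {
    for (r in 1:2) {
      samples[[sprintf("P1_%s_rep%d_ChIP", zt, r)]] <-
        make_fs(start = rep(1000, 40), end = rep(1400, 40),
                zt = zt, replicate = r)
      samples[[sprintf("P1_%s_rep%d_input", zt, r)]] <-
        make_fs(start = rep(1100, 10), end = rep(1500, 10),
                zt = zt, replicate = r, treatment = "input")
    }
  }
  ab <- target_abundance(data.frame(start = 900, end = 1600), samples, "P1")
  expect_true(all(ab$abundance == 41 / 11))

  # treat == control gives abundance 1
  samples2 <- samples
  for (k in grep("input", names(samples2), value = TRUE)) {
    samples2[[k]]$fragments <-
      samples2[[sub("input", "ChIP", k)]]$fragments
  }
  ab2 <- target_abundance(data.frame(start = 900, end = 1600), samples2, "P1")
  expect_true(all(ab2$abundance == 1))

  # brute-force overlap counting oracle on random fragments
  set.seed(14)
  st <- sample.int(9000, 300)
  samples3 <- samples
  samples3[["P1_ZT3_rep1_ChIP"]] <- make_fs(st, st + 150)
  iv <- data.frame(start = 2000, end = 3500)
  ab3 <- target_abundance(iv, samples3, "P1")
  oracle <- sum(st < iv$end & (st + 150) > iv$start)
  expect_equal(ab3$treat[ab3$zt == "ZT3" & ab3$replicate == 1], oracle)

  # a missing replicate is reported by name
  expect_error(
    target_abundance(iv, samples[-1], "P1"),
    "P1_ZT3_rep1_ChIP")
})

test_that("phase assignment applies the ANOVA and tie-separation rules", {
  ab <- function(m, sd = 0.5, n = 2, seed = 1) {
    set.seed(seed)
    data.frame(zt = rep(c("ZT3", "ZT9", "ZT15"), each = n),
               abundance = pmax(0.01, rnorm(3 * n, rep(m, each = n), sd)))
  }
  # flat means, tight replicates: excluded by the ANOVA
  flat <- assign_phase(ab(c(10, 10, 10), sd = 0.3))
  expect_equal(flat$phase, "excluded")

  # one clear morning maximum: ZT3, with p-values matching the oracles
  x <- ab(c(30, 10, 10), sd = 1, seed = 2)
  res <- assign_phase(x, log = FALSE)
  expect_equal(res$phase, "ZT3")
  expect_equal(res$anova_p, anova_oracle(x$abundance, x$zt),
               tolerance = 1e-12)
  top2 <- x[x$zt %in% c("ZT3", "ZT9"), ]
  means <- tapply(x$abundance, x$zt, mean)
  runner <- names(sort(means, decreasing = TRUE))[2]
  expect_equal(res$tie_p,
               t_oracle(x$abundance[x$zt == "ZT3"],
                        x$abundance[x$zt == runner]),
               tolerance = 1e-12)

  # two tied maxima at noise -> 0: excluded deterministically by the tie rule
  tied <- data.frame(zt = rep(c("ZT3", "ZT9", "ZT15"), each = 2),
                     abundance = c(30, 30, 30, 30, 10, 10))
  expect_equal(assign_phase(tied)$phase, "excluded")
  expect_equal(assign_phase(tied)$reason, "tie")

  # all values identical: degenerate exclusion
  degen <- data.frame(zt = rep(c("ZT3", "ZT9", "ZT15"), each = 2),
                      abundance = rep(7, 6))
  expect_equal(assign_phase(degen)$reason, "degenerate")

  # label invariance: permuting ZT labels permutes the call
  x2 <- ab(c(30, 10, 10), sd = 1, seed = 3)
  swapped <- x2
  swapped$zt <- c(ZT3 = "ZT9", ZT9 = "ZT3", ZT15 = "ZT15")[x2$zt]
  expect_equal(assign_phase(swapped)$phase, "ZT9")

  # Tukey tie rule agrees on a clear case
  expect_equal(assign_phase(x, log = FALSE, tie_method = "tukey")$phase,
               "ZT3")
})

test_that("genotype partition classes are disjoint and exhaustive", {
  t <- list(P1 = c("a", "b", "p"), P2 = c("a", "q"),
            H12 = c("a", "h", "x"), H21 = c("a", "x"))
  part <- partition_targets(t)
  expect_equal(part$shared_all, "a")
  expect_setequal(part$hybrid_specific, c("h", "x"))
  expect_setequal(part$inbred_specific, c("b", "p", "q"))
  expect_equal(part$other, character(0))

  # gene in P1 and H12 only: neither shared nor specific
  t2 <- list(P1 = "g", P2 = character(0), H12 = "g", H21 = character(0))
  expect_equal(partition_targets(t2)$other, "g")

  # disjointness on random sets
  set.seed(15)
  pool <- sprintf("g%03d", 1:60)
  t3 <- lapply(setNames(1:4, c("P1", "P2", "H12", "H21")),
               function(i) sample(pool, 25))
  p3 <- partition_targets(t3)
  classes <- p3[c("shared_all", "hybrid_specific", "inbred_specific",
                  "other")]
  expect_equal(sum(lengths(classes)),
               length(unique(unlist(t3))))
  expect_equal(anyDuplicated(unlist(classes)), 0)

  # intersection semantics are stricter than union semantics
  p_int <- partition_targets(t, semantics = "intersection")
  expect_true(all(p_int$hybrid_specific %in% part$hybrid_specific))
})

test_that("the temporal-shift Fisher test matches enumeration", {
  pt <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    genotype = rep(c("H12", "P1"), each = 100),
    phase = c(rep("ZT3", 70), rep("ZT9", 30), rep("ZT3", 40), rep("ZT9", 60)),
    stringsAsFactors = FALSE)
  st <- shift_test(pt, "H12", "P1", "ZT3")
  expect_equal(st$contingency[1, ], c(ZT3 = 70, other = 30))
  expect_equal(st$fisher_p, fisher_two_sided(70, 30, 40, 60),
               tolerance = 1e-10)

  # identical proportions and counts: p = 1
  pt2 <- pt
  pt2$phase <- rep(c(rep("ZT3", 50), rep("ZT9", 50)), 2)
  expect_equal(shift_test(pt2, "H12", "P1", "ZT3")$fisher_p, 1)

  # two-sided p symmetric under swapping the groups
  expect_equal(shift_test(pt, "H12", "P1", "ZT3")$fisher_p,
               shift_test(pt, "P1", "H12", "ZT3")$fisher_p)

  # excluded targets are dropped before testing
  pt3 <- rbind(pt, data.frame(gene_id = "gx", genotype = "H12",
                              phase = "excluded"))
  expect_equal(shift_test(pt3, "H12", "P1", "ZT3")$contingency,
               st$contingency)

  expect_error(shift_test(pt, character(0), "P1", "ZT3"), "non-empty")
})

test_that("the overlap test is the upper-tail hypergeometric", {
  r <- overlap_test(letters[1:10], letters[3:12], universe_size = 100)
  expect_equal(r$overlap, 8)
  expect_equal(r$p, hyper_upper_tail(8, 10, 100, 10), tolerance = 1e-12)

  # both sets equal to the universe: overlap forced, p = 1
  u <- sprintf("g%02d", 1:20)
  expect_equal(overlap_test(u, u, 20)$p, 1)

  # disjoint large sets in a small universe: near-1 upper tail matching
  # the enumeration
  a <- sprintf("g%02d", 1:8); b <- sprintf("g%02d", 13:20)
  r2 <- overlap_test(a, b, 20)
  expect_equal(r2$p, hyper_upper_tail(0, 8, 20, 8), tolerance = 1e-12)
  expect_equal(r2$p, 1)

  expect_error(overlap_test(sprintf("g%02d", 1:30), u, 20), "universe")
})

test_that("the 4-set permutation overlap test is seeded and calibrated", {
  set.seed(16)
  universe <- sprintf("g%03d", 1:200)
  shared <- sample(universe, 40)
  sets <- lapply(setNames(1:4, c("P1", "P2", "H12", "H21")), function(i)
    unique(c(shared, sample(universe, 30))))
  r1 <- shared_overlap_permutation(sets, universe, n_perm = 200, seed = 5)
  r2 <- shared_overlap_permutation(sets, universe, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$observed, 40)
  expect_lte(r1$p, 0.01)  # forced overlap is far beyond chance
})
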