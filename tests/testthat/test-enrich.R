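test_that("consensus scanning hits both strands exactly", {
  g <- Biostrings::DNAStringSet(c(
    chr1 = "TTTTAAATATCTGGGGCCCCAGATATTTCCCCGGGGTTTTACGTACGTAC"))
  pk <- data.frame(chrom = "chr1", start = c(0L, 16L, 36L),
                   end = c(16L, 36L, 50L))
  sc <- scan_motifs(pk, g)
  # peak 1 contains EE forward, peak 2 its reverse complement, peak 3 none
  expect_equal(unname(sc$occurrences[, "EE"]), c(1L, 1L, 0L))
  expect_equal(unname(sc$fraction["EE"]), 2 / 3)
  expect_error(scan_motifs(data.frame(chrom = "chr1", start = 40L,
                                      end = 60L), g), "bounds")
})

test_that("hit counts are invariant under reverse-complementing the genome", {
  set.seed(17)
  L <- 4000
  seq_chr <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = seq_chr))
  g_rc <- Biostrings::DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(g[[1]]))))
  s <- sample.int(L - 300, 25)
  pk <- data.frame(chrom = "chr1", start = s, end = s + 300L)
  pk_rc <- data.frame(chrom = "chr1", start = L - pk$end, end = L - pk$start)
  occ <- scan_motifs(pk, g)$occurrences
  occ_rc <- scan_motifs(pk_rc, g_rc)$occurrences
  expect_equal(unname(occ), unname(occ_rc))  # peak i mirrors peak i
  expect_equal(colSums(occ), colSums(occ_rc))
})

test_that("planted motif fractions are recovered from simulated promoters", {
  d <- sim_design(n_genes = 250, motif_plant_rate = 0.8, motif = "EE",
                  depth_per_sample = 100, seed = 19)
  sim <- simulate_genome(d)
  prom <- zeitbind:::promoter_interval(sim$genes$tss, sim$genes$strand,
                                       2000L, d$genome_length)
  pk <- data.frame(chrom = "chr1", start = prom$start, end = prom$end)
  frac <- scan_motifs(pk, sim$genome)$fraction["EE"]
  expect_lt(abs(frac - 0.8), 0.05)
  # planted promoters always hit; unplanted only by chance
  occ <- scan_motifs(pk, sim$genome)$occurrences[, "EE"]
  expect_true(all(occ[sim$genes$motif_planted] >= 1))
})

test_that("the dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(18)
  for (i in 1:10) {
    x <- sample(c("A", "C", "G", "T"), 150, TRUE)
    y <- zeitbind:::dinucleotide_shuffle(x)
    expect_equal(sort(paste0(head(y, -1), tail(y, -1))),
                 sort(paste0(head(x, -1), tail(x, -1))))
    expect_equal(y[1], x[1])
    expect_equal(y[length(y)], x[length(x)])
  }
})

test_that("motif shuffle enrichment hits its permutation floor and ceiling", {
  set.seed(20)
  # 15 random peaks, EE planted into every one
  seqs <- vapply(1:15, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
    character(1))
  seqs <- vapply(seqs, function(s)
    paste0(substr(s, 1, 50), "AAATATCT", substr(s, 59, 120)), character(1))
  g <- Biostrings::DNAStringSet(c(chr1 = paste(seqs, collapse = "")))
  pk <- data.frame(chrom = "chr1", start = seq(0, by = 120, length.out = 15),
                   end = seq(120, by = 120, length.out = 15))
  motifs <- data.frame(name = c("EE", "absent"),
                       consensus = c("AAATATCT", "ACGTACGTACGT"),
                       stringsAsFactors = FALSE)
  me <- motif_enrichment(pk, g, motifs, n_shuffles = 49, seed = 4)
  expect_equal(me$observed_fraction[me$motif == "EE"], 1)
  expect_equal(me$p[me$motif == "EE"], 1 / 50)
  # absent motif: observed fraction 0, p = 1 with the add-one correction
  expect_equal(me$observed_fraction[me$motif == "absent"], 0)
  expect_equal(me$p[me$motif == "absent"], 1)
  # seeded reproducibility
  me2 <- motif_enrichment(pk, g, motifs, n_shuffles = 49, seed = 4)
  expect_identical(me, me2)
})

test_that("GO enrichment matches the closed-form hypergeometric", {
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = universe[1:5], term_id = "GO:A")
  res <- go_enrichment(universe[1:5], universe, ann)
  expect_equal(res$p_hyper,
               choose(5, 5) * choose(15, 0) / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_hyper, hyper_upper_tail(5, 5, 20, 5),
               tolerance = 1e-12)

  # k = K = n = N: forced overlap, p = 1
  ann2 <- data.frame(gene_id = universe, term_id = "GO:B")
  expect_equal(go_enrichment(universe, universe, ann2)$p_hyper, 1)

  # hypergeometric matches enumeration across random configurations
  set.seed(21)
  for (i in 1:20) {
    N <- sample(20:60, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_upper_tail(k, K, N, n), tolerance = 1e-12)
  }

  expect_error(go_enrichment("g01", character(0), ann), "empty")
  expect_error(go_enrichment("zz", universe, ann), "subset")
})

test_that("BH-adjusted values are monotone and bounded below by raw p", {
  set.seed(22)
  universe <- sprintf("g%03d", 1:150)
  ann <- do.call(rbind, lapply(sprintf("GO:%02d", 1:12), function(t)
    data.frame(gene_id = sample(universe, sample(5:40, 1)), term_id = t)))
  res <- go_enrichment(sample(universe, 40), universe, ann)
  expect_true(all(diff(res$fdr_bh) >= -1e-12))
  expect_true(all(res$fdr_bh >= res$p_hyper - 1e-12))
  expect_true(all(res$fdr_bh <= 1))
})

test_that("a planted GO signal ranks first among tested terms", {
  first <- 0L
  for (s in 1:10) {
    d <- sim_design(n_genes = 300, depth_per_sample = 100, seed = s)
    sim <- simulate_genome(d, with_sequence = FALSE)
    bound <- unique(sim$truth$gene_id[sim$truth$bound])
    res <- go_enrichment(bound, sim$genes$gene_id, sim$go)
    if (res$term_id[1] == d$go_focal_term) first <- first + 1L
  }
  expect_gte(first, 9L)
})
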