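# Independent oracles used across the suite. Each recomputes a quantity by
# direct summation/enumeration, never through the code path under test.

# Poisson upper tail P(X >= k | lambda) by direct series summation.
poisson_upper_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  if (lambda == 0) return(0)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  total <- term
  j <- k
  repeat {
    j <- j + 1
    term <- term * lambda / j
    total <- total + term
    if (term < total * 1e-17 && j > lambda) break
  }
  total
}

# Hypergeometric upper tail P(X >= k) with K successes, N total, n draws,
# by direct summation of binomial-coefficient terms.
hyper_upper_tail <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- max(k, 0):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Two-sided Fisher exact p for the 2x2 table rbind(c(a, b), c(c, d)) by
# exhaustive enumeration over the fixed margins.
fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1))
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Per-base pileup by explicit accumulation.
brute_pileup <- function(frags, genome_length) {
  v <- numeric(genome_length)
  for (i in seq_len(nrow(frags))) {
    idx <- (frags$start[i] + 1L):frags$end[i]
    v[idx] <- v[idx] + 1
  }
  v
}

# One-way equal-variance ANOVA p-value from first principles.
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Pooled-variance two-sample t-test p-value from first principles.
t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), n1 + n2 - 2)
}

# small fragment_set builder for hand-made interval fixtures
make_fs <- function(start, end, strand = "+", genome_length = 10000L,
                    id = "s1", genotype = "P1", zt = "ZT3", replicate = 1,
                    treatment = "ChIP") {
  fragment_set(id, genotype, zt, replicate, treatment,
               data.frame(chrom = "chr1", start = as.integer(start),
                          end = as.integer(end),
                          strand = rep_len(strand, length(start)),
                          stringsAsFactors = FALSE),
               genome_length = genome_length)
}
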