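#' Reference-normalized relative expression from qPCR Ct values
#'
#' Applies the delta-Ct model: relative expression
#' `2^-(Ct_gene - Ct_reference)` per (genotype, time, replicate), the
#' reference being a stably expressed control such as 18S rRNA. Optionally
#' rescales each gene so the mid-parent value at the first time point
#' equals 1 (the plotting convention for diurnal series).
#'
#' @param ct data.frame with `gene_id`, `genotype`, `time`, `replicate`,
#'   `ct`.
#' @param reference_gene Id of the reference gene (must be present for
#'   every sample).
#' @param rescale_mpv Rescale so MPV at the first time point is 1.
#' @param parents Genotypes averaged for the MPV rescaling.
#' @return data.frame with `gene_id`, `genotype`, `time`, `replicate`,
#'   `value` (relative expression).
#' @examples
#' ct <- data.frame(gene_id = c("g", "18S"), genotype = "P1", time = 0,
#'                  replicate = 1, ct = c(21, 20))
#' relative_expression(ct, rescale_mpv = FALSE)$value  # 2^-(21-20)
#' @export
relative_expression <- function(ct, reference_gene = "18S",
                                rescale_mpv = TRUE,
                                parents = c("P1", "P2")) {
  stopifnot(all(c("gene_id", "genotype", "time", "replicate", "ct")
                %in% names(ct)))
  ref <- ct[ct$gene_id == reference_gene, , drop = FALSE]
  check_that(nrow(ref) > 0, "reference gene '%s' not in table",
             reference_gene)
  key <- function(d) paste(d$genotype, d$time, d$replicate, sep = "\r")
  ref_ct <- setNames(ref$ct, key(ref))
  x <- ct[ct$gene_id != reference_gene, , drop = FALSE]
  rk <- key(x)
  if (any(!rk %in% names(ref_ct))) {
    stop("missing reference Ct for sample(s): ",
         paste(unique(gsub("\r", "/", rk[!rk %in% names(ref_ct)])),
               collapse = ", "), call. = FALSE)
  }
  x$value <- 2^-(x$ct - ref_ct[rk])
  x$ct <- NULL
  if (rescale_mpv) {
    t0 <- min(x$time)
    for (g in unique(x$gene_id)) {
      sel <- x$gene_id == g
      p_means <- vapply(parents, function(p)
        mean(x$value[sel & x$genotype == p & x$time == t0]), numeric(1))
      scale <- mean(p_means)
      if (is.finite(scale) && scale > 0) x$value[sel] <- x$value[sel] / scale
    }
  }
  rownames(x) <- NULL
  x
}

#' Mid-parent value series
#'
#' The additive expectation for a hybrid: the pointwise mean of the two
#' parental series. Replicate-level MPV pseudo-samples are formed by
#' pairing parental replicate i with replicate i (random pairing available,
#' seeded), so downstream t-tests have replicate values on both sides.
#'
#' @param expr Expression data.frame (`gene_id`, `genotype`, `time`,
#'   `replicate`, `value`).
#' @param parents Length-2 character vector of parental genotypes.
#' @param pairing `"index"` (replicate i with i, default) or `"random"`.
#' @param seed Seed used when `pairing = "random"`.
#' @return data.frame of MPV pseudo-replicates with `genotype = "MPV"`.
#' @export
mpv <- function(expr, parents = c("P1", "P2"), pairing = c("index", "random"),
                seed = 1L) {
  pairing <- match.arg(pairing)
  p1 <- expr[expr$genotype == parents[1], , drop = FALSE]
  p2 <- expr[expr$genotype == parents[2], , drop = FALSE]
  check_that(nrow(p1) > 0 && nrow(p2) > 0, "parental series missing")
  check_that(setequal(unique(p1$time), unique(p2$time)),
             "parental time axes do not match")
  if (pairing == "random") {
    p2 <- withr::with_seed(seed, {
      do.call(rbind, lapply(split(p2, list(p2$gene_id, p2$time), drop = TRUE),
                            function(d) {
                              d$replicate <- sample(d$replicate)
                              d
                            }))
    })
  }
  k1 <- paste(p1$gene_id, p1$time, p1$replicate, sep = "\r")
  k2 <- paste(p2$gene_id, p2$time, p2$replicate, sep = "\r")
  m <- match(k1, k2)
  check_that(!anyNA(m), "parental replicate structures do not match")
  out <- p1
  out$genotype <- "MPV"
  out$value <- (p1$value + p2$value[m]) / 2
  rownames(out) <- NULL
  out
}

#' Test hybrid expression for nonadditivity against the MPV
#'
#' Per gene and time point, a two-sample Student's t-test (equal variance;
#' Welch via `var_equal = FALSE`) of the hybrid replicates against the MPV
#' pseudo-replicates. A gene/time point is called nonadditive when
#' `p < alpha`; the effect summary is `log2(F1 mean / MPV mean)`.
#'
#' @param expr Expression data.frame including the hybrid genotype.
#' @param mpv_series Output of [mpv()].
#' @param hybrid Hybrid genotype to test.
#' @param alpha Significance cutoff.
#' @param var_equal Student's (TRUE, default) or Welch's t.
#' @return data.frame with `gene_id`, `time`, `mpv`, `f1_mean`, `t_p`,
#'   `mode` (`"additive"`/`"nonadditive"`), `log2_ratio`, `degenerate`.
#' @export
nonadditivity_test <- function(expr, mpv_series, hybrid = "H12",
                               alpha = 0.05, var_equal = TRUE) {
  f1 <- expr[expr$genotype == hybrid, , drop = FALSE]
  check_that(nrow(f1) > 0, "no rows for hybrid '%s'", hybrid)
  combos <- unique(f1[c("gene_id", "time")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    gid <- combos$gene_id[i]; tp <- combos$time[i]
    xf <- f1$value[f1$gene_id == gid & f1$time == tp]
    xm <- mpv_series$value[mpv_series$gene_id == gid & mpv_series$time == tp]
    check_that(length(xf) >= 2 && length(xm) >= 2,
               "need >= 2 replicates for gene %s at time %s", gid, tp)
    degenerate <- sd(xf) == 0 && sd(xm) == 0
    if (degenerate) {
      t_p <- if (mean(xf) == mean(xm)) 1 else 0
    } else {
      t_p <- t.test(xf, xm, var.equal = var_equal)$p.value
    }
    out[[i]] <- data.frame(
      gene_id = gid, time = tp, mpv = mean(xm), f1_mean = mean(xf),
      t_p = t_p, mode = if (t_p < alpha) "nonadditive" else "additive",
      log2_ratio = if (mean(xm) > 0) log2(mean(xf) / mean(xm)) else NA_real_,
      degenerate = degenerate, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent better-parent heterosis
#'
#' `%BPH = (hybrid - best parent) / best parent x 100`, the best parent
#' being the parent with the larger mean.
#'
#' @param hybrid_values,parent1_values,parent2_values Numeric replicate
#'   vectors.
#' @return Percent BPH (a single number; negative when the hybrid falls
#'   below the better parent).
#' @examples
#' bph(c(12, 12), c(10, 10), c(8, 8))  # 20
#' @export
bph <- function(hybrid_values, parent1_values, parent2_values) {
  best <- max(mean(parent1_values), mean(parent2_values))
  check_that(best > 0, "best-parent mean must be positive")
  (mean(hybrid_values) - best) / best * 100
}
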