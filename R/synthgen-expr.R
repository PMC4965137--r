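#' Simulate qPCR-style expression tables with known heterosis modes
#'
#' Generates Ct tables for the two inbred parents and the reciprocal
#' hybrids over a time axis (zeitgeber hours by default, days after
#' planting for developmental series). Each gene gets a baseline level, a
#' diurnal cosine modulation with a random peak time, and a parental
#' divergence factor; hybrid expression equals the mid-parent value times
#' an effect factor: 1 for additive genes, `effect_size` (up) or
#' `1/effect_size` (down) at the configured `effect_times` for nonadditive
#' genes. Replicates carry multiplicative log-normal noise. The reference
#' gene (18S) is emitted at a constant Ct so the delta-Ct transform
#' recovers the planted relative levels.
#'
#' @param n_genes Number of test genes.
#' @param modes Optional character vector of per-gene modes (`additive`,
#'   `nonadditive-up`, `nonadditive-down`); drawn from `mode_probs`
#'   otherwise.
#' @param mode_probs Mode probabilities when `modes` is not given.
#' @param effect_size Fold deviation of F1 from MPV at `effect_times`.
#' @param effect_times Time points (same units as `times`) at which
#'   nonadditive genes deviate.
#' @param times Time axis.
#' @param n_reps Replicates per (genotype, time).
#' @param noise_cv Replicate coefficient of variation (log-normal sdlog).
#' @param ref_ct Ct of the reference gene.
#' @param reference_gene Reference gene id.
#' @param seed Integer seed.
#' @return A list with `ct` (data.frame: `gene_id`, `genotype`, `time`,
#'   `replicate`, `ct`, including the reference gene) and `truth`
#'   (data.frame: `gene_id`, `mode`).
#' @export
simulate_expression <- function(n_genes = 12, modes = NULL,
                                mode_probs = c(additive = 0.8,
                                               `nonadditive-up` = 0.1,
                                               `nonadditive-down` = 0.1),
                                effect_size = 2, effect_times = 3,
                                times = seq(0, 21, by = 3), n_reps = 3,
                                noise_cv = 0.1, ref_ct = 15,
                                reference_gene = "18S", seed = 1L) {
  withr::with_seed(seed, {
    gene_id <- sprintf("expr%04d", seq_len(n_genes))
    if (is.null(modes)) {
      modes <- sample(names(mode_probs), n_genes, replace = TRUE,
                      prob = mode_probs)
    }
    check_that(length(modes) == n_genes,
               "'modes' must have one entry per gene")
    base <- rlnorm(n_genes, 0, 0.3)
    divergence <- rlnorm(n_genes, 0, 0.2)
    peak_time <- sample(times, n_genes, replace = TRUE)

    grid <- expand.grid(time = times, replicate = seq_len(n_reps),
                        KEEP.OUT.ATTRS = FALSE)
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      profile <- 1 + 0.6 * cos(2 * pi * (grid$time - peak_time[i]) / 24)
      p1 <- base[i] * profile
      p2 <- base[i] * divergence[i] * profile
      eff <- rep(1, nrow(grid))
      if (modes[i] == "nonadditive-up") {
        eff[grid$time %in% effect_times] <- effect_size
      } else if (modes[i] == "nonadditive-down") {
        eff[grid$time %in% effect_times] <- 1 / effect_size
      }
      f1 <- (p1 + p2) / 2 * eff
      noise <- function(x) x * rlnorm(length(x), 0, noise_cv)
      rows[[i]] <- data.frame(
        gene_id = gene_id[i],
        genotype = rep(GENOTYPES, each = nrow(grid)),
        time = rep(grid$time, 4), replicate = rep(grid$replicate, 4),
        value = c(noise(p1), noise(p2), noise(f1), noise(f1)),
        stringsAsFactors = FALSE)
    }
    expr <- do.call(rbind, rows)
    expr$ct <- ref_ct - log2(expr$value)
    ref <- unique(expr[c("genotype", "time", "replicate")])
    ref <- data.frame(gene_id = reference_gene, ref, ct = ref_ct,
                      stringsAsFactors = FALSE)
    ct <- rbind(expr[c("gene_id", "genotype", "time", "replicate", "ct")],
                ref)
    rownames(ct) <- NULL
    list(ct = ct,
         truth = data.frame(gene_id = gene_id, mode = modes,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate luminescence rhythm traces with known labels
#'
#' Rhythmic traces are damped cosines (`amplitude * exp(-damping * t) *
#' cos(2 pi t / period + phase)`) over a baseline, plus Gaussian noise;
#' arrhythmic traces are Gaussian noise over a slow linear drift.
#'
#' @param n_rhythmic,n_arrhythmic Trace counts per class.
#' @param period True circadian period (h) of the rhythmic class.
#' @param damping Exponential damping rate (1/h).
#' @param amplitude Oscillation amplitude.
#' @param baseline Constant baseline level.
#' @param noise_sd Gaussian noise sd (same units as the signal).
#' @param drift Maximum absolute slope (units/h) of the arrhythmic drift.
#' @param duration Trace length (h); a warning is issued below 2 periods.
#' @param dt Sampling interval (h).
#' @param seed Integer seed.
#' @return data.frame with `trace_id`, `time`, `value`, `label`
#'   (`"rhythmic"`/`"arrhythmic"`), `true_period` (NA for arrhythmic).
#' @export
simulate_traces <- function(n_rhythmic = 10, n_arrhythmic = 10, period = 24,
                            damping = 0.005, amplitude = 1, baseline = 10,
                            noise_sd = 0.1, drift = 0.02, duration = 120,
                            dt = 1, seed = 1L) {
  if (duration < 2 * period) {
    warning("trace duration below two periods: period not resolvable")
  }
  tt <- seq(0, duration, by = dt)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_rhythmic)) {
      phase <- runif(1, 0, 2 * pi)
      val <- baseline + amplitude * exp(-damping * tt) *
        cos(2 * pi * tt / period + phase) + rnorm(length(tt), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        trace_id = sprintf("rhy%03d", i), time = tt, value = val,
        label = "rhythmic", true_period = period, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_arrhythmic)) {
      slope <- runif(1, -drift, drift)
      val <- baseline + slope * tt + rnorm(length(tt), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        trace_id = sprintf("arr%03d", i), time = tt, value = val,
        label = "arrhythmic", true_period = NA_real_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
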