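# zeitbind

Diurnal transcription-factor ChIP-seq phase-shift analysis for
inbred-vs-hybrid comparisons, with a ground-truth simulator for every
stage.

## The problem

Circadian MYB transcription factors of the CCA1/LHY family bind their
targets with a pronounced time-of-day preference. In crop hybrids, a
*temporal shift* of that binding toward the early morning — more targets
maximally bound at ZT3 (three hours after lights-on) in the F1 hybrids
than in their inbred parents — has been proposed as a mechanism linking
clock reprogramming to growth heterosis. Detecting such a shift from a
diurnal ChIP-seq design (4 genotypes: inbreds P1/P2 and reciprocal
hybrids H12/H21, sampled at ZT3/ZT9/ZT15 with 2 replicates plus matched
inputs) requires a chain of decisions — deduplication, depth
normalization, peak calling, replicate concordance, target assignment,
phase assignment, and genotype contrasts — each of which this package
makes explicit, testable, and reusable. Companion modules quantify the
expression side of heterosis (mid-parent-value tests on qPCR series,
%BPH) and circadian rhythmicity of reporter traces (FFT-NLLS period and
relative amplitude error).

## The methods at a glance

* **Depth normalization** — after removing PCR duplicates (identical
  `(chrom, start, end, strand)` fragments), every sample is down-sampled
  without replacement to the smallest library: samples of 4, 5, 6 and 7
  thousand (or million) fragments all end at the smallest count.
* **Peak calling** — a Poisson local-background test: position *x* with
  treatment count *k* is scored by `P(X >= k | lambda_local)` where
  `lambda_local = max(lambda_genome, lambda_1kb, lambda_5kb,
  lambda_10kb)` is estimated from the matched input around *x*
  (cutoff p < 1e-3). Peaks present in both replicates (>= 1 bp overlap,
  union span) are merged across time points into per-genotype master
  peaks.
* **Targets and phases** — genes within 10 kb of a master peak are
  targets. Per target, binding abundance at each ZT is the pseudocounted
  treatment/control fragment-count ratio over the master-peak interval;
  a one-way ANOVA across ZTs (p < 0.05) plus a top-vs-runner-up
  separation rule assigns the phase, and targets with indistinguishable
  abundance at two or more time points are excluded.
* **Contrasts** — a two-sided Fisher's exact test compares the fraction
  of ZT3-phased targets between the pooled hybrids and pooled inbreds;
  hypergeometric (and permutation) tests score target-set overlaps;
  genomic-feature and GO enrichments use Fisher/hypergeometric tests
  with Benjamini–Hochberg control.
* **Motifs** — exact both-strand scanning of the reported consensus
  motifs (evening element `AAATATCT`, CCA1-binding site `AAAAATCT`, Dof
  `AAAGC`) with a dinucleotide-preserving shuffle background.
* **Heterosis** — relative expression `2^-(Ct_gene - Ct_18S)`, the
  mid-parent value MPV = (P1 + P2)/2, Student's t per time point for
  nonadditivity, `log2(F1/MPV)` effect sizes, and
  `%BPH = (hybrid - best parent)/best parent x 100`.
* **Rhythms** — FFT-seeded nonlinear least squares fits
  `x(t) = c0 + c1 t + sum_i a_i e^(-d_i t) cos(2 pi t / tau_i + phi_i)`;
  the relative amplitude error (RAE) of the circadian component
  (15–40 h window) classifies traces, RAE > 0.6 meaning arrhythmic.

Everything runs against the built-in simulator (`sim_design()`,
`simulate_genome()`, `simulate_chip_fragments()`,
`simulate_expression()`, `simulate_traces()`), which plants known
binding phases, motifs, GO labels, expression modes, and rhythm
parameters, so every stage can be checked against its truth.

## Worked example

```r
library(zeitbind)

design <- sim_design(n_genes = 25, depth_per_sample = 12000, seed = 33)
sim <- simulate_genome(design, with_sequence = FALSE)
res <- run_binding_pipeline(sim)

vapply(res$targets, length, integer(1))
#>  P1  P2 H12 H21
#>  11  11  14  14

res$shift$ZT3$contingency
#>      phase
#> group ZT3 other
#>     a  16     6
#>     b   9    10

head(res$phase_table[res$phase_table$phase != "excluded", ], 4)
#>    gene_id genotype     anova_p      tie_p phase  mean_ZT3  mean_ZT9 mean_ZT15
#> 1 gene0001       P1 0.004806375 0.03332942   ZT3 4.0817669 1.3928571 0.7889401
#> 3 gene0006       P1 0.015714142 0.04028564  ZT15 0.9599359 0.9032258 6.4250000
#> 4 gene0011       P1 0.012395366 0.01224807   ZT9 1.1366048 4.6373626 0.8711485
#> 6 gene0014       P1 0.006339348 0.01074922   ZT9 0.9952978 4.8420699 1.2966667
```

Each genotype recovers its planted targets; per target the table shows
the ANOVA p-value, the tie-rule p-value, the assigned phase, and the
mean abundance (fold over input) at each ZT — e.g. `gene0001` is bound
4.1-fold over input at ZT3 and near background later in the day, so its
phase is ZT3. The `shift` element contrasts the pooled hybrids (row `a`,
here 16/22 = 73% of phased targets at ZT3) against the pooled inbreds
(row `b`, 9/19 = 47%); at this toy size the Fisher p-value is 0.12,
while the full-scale recovery runs in the validation suite separate the
same planted compositions (0.65 vs 0.40) at p < 1e-13.

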