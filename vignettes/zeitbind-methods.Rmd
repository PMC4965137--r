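---
title: "zeitbind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zeitbind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what the package computes, the assumptions behind
each stage, the parameters that matter, and where the design was
genuinely open. The companion README shows a worked example; the test
suite and `scripts/acceptance.R` compute every empirical claim made
here.

# The experimental design being modeled

The pipeline targets a diurnal ChIP-seq comparison of a morning-phased
MYB transcription factor across four genotypes — two inbred parents
(`P1`, `P2`) and their reciprocal F1 hybrids (`H12`, `H21`) — sampled at
three zeitgeber times (ZT3, ZT9, ZT15; ZT0 = lights-on), two biological
replicates each, every ChIP sample with a matched input. The scientific
question is whether the hybrids' binding targets are *phase-shifted*
toward the early morning relative to the inbreds, and how that shift
relates to nonadditive (mid-parent-deviating) expression and to
circadian rhythmicity.

# Fragment-space analysis

All ChIP data are handled as mapped fragment intervals (0-based,
half-open), not reads: paired-end sequencing determines both fragment
ends, so after alignment the fragment is the natural unit, and every
downstream statistic (coverage, peak calls, abundances) is a function of
fragment intervals alone. Alignment itself is out of scope; the
simulator emits fragments directly, and user data can enter as BED of
mapped fragments. One consequence is a single shared coordinate system
for all genotypes — allele-resolved mapping, where used upstream, does
not change any statistic computed here.

## Deduplication and down-sampling

PCR duplicates are fragments identical in `(chrom, start, end, strand)`
— the fragment-space equivalent of paired-end `samtools rmdup`. Depth is
then equalized by down-sampling every sample, uniformly without
replacement, to the smallest deduplicated count, which keeps peak
numbers comparable across genotypes and time points (the alternative —
scaling — would leave the Poisson calling statistics depth-dependent).
By default ChIP and input samples are pooled into a single min-count
normalization; whether inputs should join the pool is genuinely
ambiguous, so `chip_only = TRUE` restricts the pool to ChIP samples.

## Peak calling

The caller is a from-scratch implementation of the Poisson
local-background test popularized by MACS: at each position the
treatment count $k$ is scored with the upper tail
$P(X \ge k \mid \lambda_{\mathrm{local}})$, where

$$\lambda_{\mathrm{local}} = \max(\lambda_{\mathrm{genome}},
\lambda_{1\mathrm{kb}}, \lambda_{5\mathrm{kb}},
\lambda_{10\mathrm{kb}})$$

is estimated from the matched input in centered windows. The max rule
makes the test conservative wherever the input is locally elevated. The
per-base cutoff is `p_cut = 1e-3`. Contiguous significant positions
within `merge_gap = 100` bp merge into peaks; peaks shorter than
`min_length = 150` bp are dropped (both exposed — the merge/length
conventions are not dictated by the model). No fragment-size model is
built: true fragments are available, so the read-shifting step of
read-based callers is unnecessary. Replicate concordance keeps peaks
overlapping (>= 1 bp, fraction configurable) in both replicates, with
the union span retained so no signal is clipped for abundance
measurement; per-genotype master peaks are the interval union across
time points, tagged with the contributing ZTs.

With treatment equal to control, the expected significant-base fraction
stays below `p_cut` (the discrete Poisson tail plus the max rule are
conservative); the validation suite measures this over 50 seeded
50-kb experiments, and checks the per-base p-values against an
independent series-summation oracle to 1e-10.

## Targets, abundance, and phase

Genes within 10 kb of a master peak (distance from the gene span;
TSS-centric mode available) are targets, a multi-gene peak counting for
all its genes. Binding abundance of a target at one ZT and replicate is

$$\mathrm{abundance} = \frac{\text{treatment fragments in master peak} + c}
{\text{input fragments in master peak} + c}, \qquad c = 1,$$

a fold-over-input ratio; the pseudocount keeps small input counts from
exploding the ratio. The phase rules follow the two-stage criterion:
a one-way equal-variance ANOVA across the three ZT groups must reject at
$\alpha = 0.05$, and the top time point must be separated from the
runner-up (two-sample Student's t at the same $\alpha$; Tukey's HSD
available). Targets failing either rule — including any with the same
abundance at two or more time points — are excluded from the
phase-shift analysis. Both tests run on log2 abundances by default:
the abundance is a ratio of counts, whose log is variance-stabilized,
and with two replicates per ZT (error df = 2, critical |t| = 4.3) the
raw-scale test would be dominated by the ratio's skew. `log = FALSE`
restores raw-scale testing.

## Contrasts

The headline contrast pools the hybrids and pools the inbreds and runs a
two-sided Fisher's exact test on (phase == ZT vs not) x (group); per-pair
contrasts are available through the same function. Target-set overlaps
use the upper-tail hypergeometric; for the four-set shared-target count,
a seeded permutation test (each set redrawn uniformly from the universe)
supplements the pairwise tests, since no closed form is convenient.
Sidedness deserves a note: two-sided is the default because the shift
direction is a finding, not an assumption.

# Motif and GO enrichment

Only the reported consensus strings are scanned (EE `AAATATCT`, CBS
`AAAAATCT`, Dof `AAAGC`), exactly, on both strands — no position-weight
matrices, because consensus strings are all the upstream evidence
provides, and no de novo discovery. The enrichment background is an
Altschul–Erikson dinucleotide-preserving shuffle of each peak sequence
(exact dinucleotide multiset retained), which controls for the
AT-richness that plagues plant promoter scans; the empirical p-value
uses the add-one correction, so its floor is $1/(n_{\mathrm{shuffles}}+1)$.
GO enrichment is a flat per-term upper-tail hypergeometric with
Benjamini–Hochberg correction across tested terms (`min_term_size = 3`);
no DAG propagation — annotations are taken as given, and the universe
defaults to all annotated genes supplied.

# Expression heterosis

Relative expression uses the delta-Ct model $2^{-(Ct_g - Ct_{ref})}$
against a stable reference (18S rRNA by convention); efficiency-corrected
models are out of scope. The mid-parent value is the additive
expectation; replicate-level MPV pseudo-samples pair parental replicate
$i$ with replicate $i$ (the natural pairing when replicates share
harvests; random pairing is available and seeded), giving the
nonadditivity t-test replicate values on both sides. The test is
Student's equal-variance t per gene and time point, with
$\log_2(\mathrm{F1}/\mathrm{MPV})$ as the effect summary, and
%BPH = (hybrid − best parent)/best parent × 100 for growth data.

# Rhythm estimation

Traces are fit by FFT-seeded nonlinear least squares: after linear
detrending, the strongest remaining spectral peak seeds a damped cosine
component, all parameters are refit jointly (Levenberg–Marquardt, box
bounds: period positive, damping in [0, 0.5] h⁻¹), and components are
added greedily while residual variance drops by more than 1%, up to 4
components. Damped (not pure) cosines reflect the amplitude decay of
reporter rhythms under constant light. The relative amplitude error is
the half-width of the amplitude's approximate 95% confidence interval
(from the fit covariance, t-quantile at residual df) divided by the
amplitude, for the component inside the 15–40 h circadian window; this
is an approximation to the joint-confidence RAE of classic rhythm
software, whose exact construction is unpublished, and it reproduces the
operational behavior: clean rhythms give RAE near 0, noise gives RAE
near or above 1, and RAE > 0.6 classifies a trace arrhythmic. When no
component lands in the window the RAE is set to 1. Two numerical
details: parameters pinned at a box bound (typically damping at 0) make
the full Hessian singular, so standard errors are computed on the free
block; and once the fit is numerically exact (RSS below 1e-12 of the
trace variance) component addition stops, since further "components"
would only chase rounding error.

# The synthetic-data generator

`sim_design()` fixes the study conditions: 4 genotypes x 3 ZTs x 2
replicates + inputs, 400-bp mean fragments, and phase-probability
vectors (hybrids 0.65/0.20/0.15, inbreds 0.40/0.35/0.25 over
ZT3/ZT9/ZT15) that plant a morning-shifted hybrid composition. Genes sit
on a 20-kb spacing grid (so neighboring windows cannot collide), strands
random, each with a 2-kb promoter, 200-bp 5'UTR and 2.5-kb CDS.
Enrichment is a Gaussian bump of fragment centers (sd 200 bp, so the
bump footprint matches the 400-bp fragment scale) over the promoter
midpoint, with the extra-fragment count calibrated so expected summit
coverage equals occupancy x background. Occupancy defaults to 10-fold
at the planted phase and background level elsewhere: a strong, realistic
TF peak, and — by a pre-registered power analysis — the level at which
two replicates give the df-2 tie rule a noncentrality around 9, so that
clear peaks are rarely excluded. `depth_per_sample = 200000` on the
default desk-scale genome gives ~9x fragment coverage (~30 input
fragments per kilobase-scale window), the count scale that makes the
abundance ratios informative; the original maize-scale libraries cannot
be reproduced at desk scale, so the simulator preserves per-locus
information content rather than genome-wide totals. PCR duplicates are
exact copies appended at rate d/(1-d) so a fraction d of emitted
fragments are duplicates.

What the generator does *not* emulate: base-level reads and sequencing
error (fragments are planted directly), mappability structure and
repeats (background is uniform), chromatin-driven input bias,
allele-specific binding, and inter-replicate biological variance beyond
Poisson counting noise. Passing recovery tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to every artifact of real libraries.

Expression tables plant additive, nonadditive-up and nonadditive-down
genes (F1 = MPV x effect at configured time points, 2-fold by default,
log-normal replicate noise at 10% CV, 3 replicates), emitted as Ct
values with a constant-Ct 18S reference so the delta-Ct transform
recovers the planted levels exactly. Luminescence traces are damped
cosines plus Gaussian noise, or noise over a slow linear drift for the
arrhythmic class.

# Validation problem sizes

The package's validation suites run at sizes chosen to make their
statistical assertions sharp while staying desk-scale: 50 seeded
recovery runs at 400 genes x 4 genotypes x 2 replicates for
phase-composition recovery (+-5-point bands); one seeded 200-replicate
Monte Carlo experiment for the null calibration of the shift contrast;
50 seeded 50-kb genomes for the caller's false-positive bound; 250
promoters for motif-fraction recovery; 500/200 genes for heterosis
size/power; and 100 seeded white-noise traces for the arrhythmicity
bar. The acceptance script re-runs scaled versions of the same analyses
from a single command-line seed.

# Known limitations

* Single-chromosome coverage operations: multi-chromosome inputs are
  handled per chromosome by the caller's wrappers, but the simulator
  emits one chromosome.
* The abundance statistic attributes all master-peak signal to every
  gene the peak is assigned to; closely spaced co-targets share
  abundance.
* Consensus-only motif matching misses degenerate sites a PWM would
  score.
* The RAE is a per-parameter, not joint-confidence, approximation.
* Fisher/hypergeometric tests treat genes as exchangeable; no
  correction for gene length or peak width is applied to the GO
  universe.
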