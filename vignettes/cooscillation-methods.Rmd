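---
title: "Detecting co-oscillation of chromatin accessibility and transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting co-oscillation of chromatin accessibility and transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(chronoaccess)
library(dplyr)
```

## The problem

Under free-running conditions (constant light after photoperiodic
entrainment), circadian clocks keep driving rhythmic transcription. A
natural question in plant chromatin biology is how much of that rhythm is
accompanied — and potentially gated — by rhythmic chromatin accessibility at
the cis-regulatory regions of the same genes. Given a replicated time course
of ATAC-seq accessibility over accessible chromatin regions (ACRs) and
RNA-seq expression over genes, sampled at six Zeitgeber times four hours
apart (ZT24–ZT44, one subjective day), `chronoaccess` identifies the genes
whose expression oscillates *in synchrony* with the accessibility of a
nearby ACR, orders them by circadian phase, and supports three follow-up
analyses: differential accessibility in clock-mutant genotypes, motif-based
assembly of a clock regulatory network, and the geographic distribution of
cis-regulatory haplotypes.

## The screening funnel

The core procedure is a funnel that successively restricts the feature
universe:

1. **Floors.** ACRs lose the brightest fraction (default top 0.5% by
   maximum per-timepoint mean signal; these are typically saturated or
   artifactual peaks), everything below 10 RPKM at *all* six time points,
   and everything whose maximum falls below the 5th percentile of the
   surviving maxima. Genes below 1 TPM at all time points are dropped.
2. **Fluctuation.** For each feature the six per-timepoint means (replicates
   averaged) give a percent coefficient of variation,
   `CV = 100 · sd(means)/mean(means)` with the sample sd (n−1). Features
   with `CV ≥ 13` (ACRs) or `CV ≥ 16` (genes) are *fluctuating*; a
   percentile mode (`"percentile:10"`) derives the threshold from the CV
   distribution instead and records the realized value.
3. **Association.** A gene and an ACR are associated when the ACR overlaps
   the gene body (UTRs included) or lies within 1 kb of the TSS or TES.
   The same rule drives the genic/proximal/distal (gACR/pACR/dACR)
   classification, with precedence gACR > pACR > dACR so the classes
   partition the input.
4. **COG.** Fluctuating gene and ACR z-profiles are clustered jointly by
   fuzzy c-means in one profile space, so cluster labels are shared. An
   associated pair enters the co-oscillation group when both members are
   *core* members (top membership ≥ 0.3) of the same cluster.
5. **CCOG.** A pair survives into the core co-oscillation group when the
   Spearman correlation of its timepoint-mean profiles is ≥ 0.6. A gene is
   a CCOG gene when at least one of its pairs passes.
6. **Phase partition.** CCOG gene z-profiles are refit with fuzzy c-means
   (default 11 clusters); each cluster's peak ZT is the grid argmax of its
   mean member profile, clusters peaking at ZT24–32 are subjective-light
   and ZT36–44 subjective-dark, and clusters are renumbered by ascending
   peak time.

### Fuzzy c-means

`fcm_fit()` minimizes the fuzzified within-cluster sum of squares
$\sum_i \sum_c u_{ic}^m \lVert x_i - v_c\rVert^2$ by alternating the
standard membership update
$u_{ic} = 1/\sum_k (d_{ic}/d_{ik})^{2/(m-1)}$ and the weighted center
update, stopping when the maximum center shift drops below `tol` (1e-6).
Because the objective is non-convex, fitting runs `n_restarts = 10` seeded
restarts from random feature rows and keeps the best objective; on desk-size
instances this reproducibly reaches the optimum found by 500 independent
random restarts of an external optimizer. The fuzzifier defaults to
`m = 1.25`, the customary choice for standardized expression profiles: with
six-dimensional z-profiles, `m = 2` washes memberships out, while values
near 1 approach hard k-means. Membership rows sum to 1 at every iteration
and the objective trace is non-increasing; both are exposed on the fitted
object and asserted in the test suite. A feature coincident with a center
receives membership 1 there by convention. Ties in the core-membership
argmax go to the lowest cluster index.

Genes and ACRs are clustered *jointly* so that "same cluster" is
well-defined for a pair; a separate-fits mode (labels matched by nearest
centers) is available through `select_cog(acr_model = )` for users who
prefer to cluster the two assays independently.

### Design choices that were genuinely open

- **Synchronization statistic.** The CCOG gate uses the Spearman
  coefficient itself (ρ ≥ 0.6) rather than ρ²; `select_ccog(square =
  TRUE)` switches to a signed-ρ² reading for sensitivity analysis.
- **Distance convention.** Distances from an ACR to a TSS/TES are gap
  lengths (bases strictly between the interval and the point, 0 for
  overlap or adjacency), the native metric of the interval machinery used
  throughout; "within 1 kb" therefore means gap ≤ 1000.
- **Rounding.** Funnel percentages are rounded half-up to one decimal,
  matching how such tables are conventionally printed.
- **CV estimator.** The sample sd (n−1) over the six per-timepoint means,
  on a percent scale; z-profiles use the population sd, the usual
  standardization for profile heatmaps. Both choices are recorded here
  because thresholds like CV ≥ 13 are only meaningful relative to them.
- **Both low floors.** The absolute RPKM < 10 floor and the 5th-percentile
  floor are applied sequentially; the redundancy is harmless and the
  realized percentile value is logged so runs can be compared.
- **Idempotency.** The percentile-based removals are data-driven, so
  re-running a filter on its own output with thresholds recomputed would
  trim further; re-imposing the *recorded* realized thresholds
  (`percentile_value =`) is the idempotent form, and the screen result
  carries those values for exactly this purpose.
- **ATG anchoring.** Promoter-relative intervals ("−1,654 to −924 bp
  upstream of ATG") anchor at the translation start when a CDS coordinate
  is supplied and fall back to the TSS with a warning otherwise
  (`fallback_tss = FALSE` turns the fallback into an error).

## Differential accessibility in clock mutants

`test_differential()` compares wild-type and mutant replicate counts per
ACR at one time point. Counts are normalized by median-of-ratios size
factors, and a Wald statistic is formed on the log mean ratio with the
negative-binomial variance `mu + a·mu²`. The common dispersion `a` is a
method-of-moments estimate: the mean across features of
`(pooled within-group variance − mean)/mean²`, which is unbiased for `a`
feature-wise and stable when averaged over thousands of features. The
decision rule is the screening rule of interest: a site is *induced* or
*repressed* only when `p < 0.05` **and** every per-replicate fold change
(mutant replicate k over wild-type replicate k) exceeds 1.5 in the same
direction; "identified in both biological replicates" is read as this
per-replicate gate, since a per-replicate test with n = 1 is not
well-defined. Zero denominators take a pseudo-count of 1 and are flagged.
This is intentionally a minimal count test, not a reimplementation of a
full differential framework (no shrinkage, no outlier filtering): the unit
tests verify symmetry under label swap, type-I control (≤ 0.07 empirical at
α = 0.05 on 2,000 null NB features), ≥ 90% power on planted 3× effects at
dispersion 0.05 with 2+2 replicates, and agreement with a parametric
resampling oracle on decisive features.

`genome_average_shift()` reports the percent change of mean signal between
genotypes over any region set — genome-wide or restricted to the CCOG — at
one time point, the statistic behind statements like "accessibility 33%
higher at ZT24".

## Motif scanning and the clock network

`pwm_scan()` scores both strands with plain log2-odds against the PWM
background; `N` contributes zero. The default hit threshold is 80% of the
motif's maximum attainable score — a conventional stringency for short
plant motifs, configurable per call. Enrichment is a one-sided Fisher exact
test on sequences-with-hit counts against a background set, BH-adjusted
across motifs; the default background is an Altschul–Erickson dinucleotide
shuffle of the foreground, preserving exact dinucleotide composition.
`build_network()` runs the enrichment per clock gene over the sequences of
its associated ACRs and draws a TF → gene edge for every motif with raw
`p < 0.005` (the adjusted value is also reported and can gate instead via
`adjusted = TRUE`; the threshold is configurable because whether such
screens gate on raw or adjusted p is often left unstated).
`summit_offset()` measures the signed, strand-normalized distance from each
ACR summit to the nearest histone-mark peak summit within 2 kb, positive
meaning downstream — the geometry behind "H3K9ac/H3K27ac summits sit on
average ~250 bp downstream of ACRs".

## Haplotype geography

`extract_haplotypes()` reads biallelic SNPs inside a cis-regulatory
interval from a VCF and builds two allele strings per accession from phased
or homozygous genotypes. Unphased heterozygotes cannot be assigned
haplotypes and are excluded from labeling with a reported tally — the
analysis concerns homozygous haplotypes, so this exclusion mirrors the
scientific question rather than imputing phase. Labels H01, H02, … follow
descending chromosome counts with lexicographic tie-breaks (making labels
invariant to accession order); haplotypes below `min_frequency = 0.01` of
chromosomes pool into `"rare"`, a conventional cutoff for "reliable"
haplotypes that is exposed as a parameter because such cutoffs are rarely
printed. `group_frequencies()` stratifies proportions over homozygous
accessions by geographic region or germplasm class, and `latitude_trend()`
is the Spearman correlation between the south-to-north group rank and a
per-group rate — region order stands proxy for latitude because panels like
this are delimited by rivers, not coordinates.

## The synthetic study

`simulate_study()` builds a complete desk-scale study with known ground
truth:

- **Geometry.** Genes (2.2–3 kb) on one chromosome with 8 kb intergaps;
  ACRs of 200 bp placed so the planted gACR/pACR/dACR class is exactly what
  `classify_acrs()` computes (class mix defaults 15.6/48.5/35.9%, a typical
  genome-wide distribution). One chromosome suffices for every operator and
  keeps fixtures readable.
- **Rhythms.** Each cell is
  `max(0, baseline + amplitude·cos(2π(t − phase)/period) + ε)`,
  `ε ~ N(0, noise_sd²)` independent per cell, truncated at zero because
  RPKM/TPM are non-negative. A cosine is the simplest model matching
  smooth single-peak circadian profiles and admits closed-form checks.
  Phases come from the six grid offsets, so every planted peak lies on a
  sampled ZT. Defaults: baselines uniform on 20–40 signal units (so floors
  bite only where intended), amplitude 10, `noise_sd` 0.5 (5% of
  amplitude), 3 replicates, 40% of genes oscillating — the recovery regime
  the package is validated in. Genic/proximal ACRs of oscillating genes
  are *coupled*: they share the host's phase exactly, and these pairs are
  the recovery ground truth.
- **Genotype effects.** `simulate_mutant()` rescales the expected signal
  at selected time points before fresh noise, e.g. a 1.33× multiplier at
  ZT24. `simulate_differential_counts()` draws NB counts with a common
  dispersion for the count-test checks.
- **ChIP summits.** One peak per ACR at a planted downstream offset
  (default 250 bp, Gaussian jitter sd 30 bp), strand decided by the host
  gene.
- **Haplotypes.** `simulate_vcf()` writes a plain-text VCF with per-group
  haplotype frequency spectra and accession metadata (region and germplasm
  labels), with a configurable homozygosity rate.

What the generator deliberately does **not** emulate: read-level sampling
noise (values are normalized signals, not reads), peak-calling artifacts,
linkage disequilibrium, multi-chromosome structure, non-sinusoidal or
asymmetric waveforms, and amplitude heterogeneity across features. Passing
tests therefore demonstrate that the *procedure* recovers planted structure
under its stated noise model — they do not certify performance on real
sequencing data, where replicate noise is not Gaussian on the normalized
scale (no noise model for biological replicates is available to plant one).

### Problem sizes and what the checks show

The validation suite runs the full funnel on 1,000 genes and 1,500 ACRs
(about 390 planted coupled pairs), where it recovers ≥ 95% of planted pairs
as CCOG and places every cluster peak on the planted phase's grid point;
clustering optimality is checked on a 12-point instance against 500
independent restarts; differential error rates use 2,000 null and 2,000
spiked features. These sizes make every property check exact or
statistically decisive while keeping a complete run in seconds. The
recovery experiments cluster with c = 6 — the number of planted phases —
because recovery of a 6-phase truth is what is being measured; real
analyses default to 11 clusters, where adjacent-phase profiles are split
more finely.

```{r example}
sim <- simulate_study(n_genes = 200, n_acrs = 300, seed = 7)
assoc <- associate_acrs(sim$acrs, sim$genes)
acc <- filter_accessibility(sim$acr_signal)
expr <- filter_expression(sim$gene_signal)
ap <- filter(compute_profiles(sim$acr_signal), feature_id %in% acc$kept_ids)
gp <- filter(compute_profiles(sim$gene_signal), feature_id %in% expr$kept_ids)
asp <- split_fluctuating(ap, 13)
gsp <- split_fluctuating(gp, 16)
joint <- bind_rows(
  filter(gp, feature_id %in% gsp$fluctuating_ids),
  filter(ap, feature_id %in% asp$fluctuating_ids)
)
fit <- fcm_fit(joint, n_clusters = 6, seed = 1)
cog <- select_cog(fit, filter(
  assoc, gene_id %in% gsp$fluctuating_ids,
  acr_id %in% asp$fluctuating_ids
))
ccog <- select_ccog(cog, gp, ap)
part <- partition_ccog(ccog, gp, n_clusters = 6, seed = 1)
part$clusters
```

## Known limitations

- Six time points over one cycle cannot support period estimation or
  formal rhythmicity tests (JTK_CYCLE-style); the CV screen is a
  fluctuation filter, not a rhythmicity test, and that is all the sampling
  design permits.
- The joint-clustering reading of "same cluster" is the minimal one; if
  gene and ACR assays were clustered separately in the original analysis,
  core-pair composition could differ at the margins (the separate-fits
  mode exists to probe this).
- The NB Wald test with a single common dispersion will be anti-
  conservative if dispersion varies strongly across features; for real
  count data a per-feature shrinkage estimator is preferable.
- Haplotype extraction trusts the VCF's phasing; no statistical phasing or
  imputation is attempted.
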