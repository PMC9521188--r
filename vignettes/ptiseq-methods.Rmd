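---
title: "Methods: time-course PTI transcriptome analysis with ptiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course PTI transcriptome analysis with ptiseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptiseq)
```

## The problem

When a plant recognizes a microbe-associated molecular pattern (MAMP) such
as the flagellin epitope flg22, it mounts pattern-triggered immunity (PTI):
a transcriptional reprogramming that unfolds over hours, inducing defense
genes while transiently shutting down photosynthesis. A standard way to
characterize this response is a baseline-anchored RNA-seq time course —
leaf tissue sampled at, say, 0, 0.5, 1, 3, 6 and 12 h after elicitor
treatment with three biological replicates — followed by a fixed analysis
recipe:

1. call genes differentially expressed at each time point versus the 0 h
   baseline (**DEGs**);
2. z-scale the DEG time profiles and cluster them with k-means, using the
   gap statistic to assess the number of clusters;
3. summarize each cluster (direction, peak time) and pick marker genes;
4. ask which functional annotations — GO terms, transcription-factor (TF)
   families, and promoter cis-regulatory elements such as the W-box — are
   over-represented in each cluster, by one-sided hypergeometric tests.

`ptiseq` implements this recipe end to end as composable tibble-in,
tibble-out functions, together with a synthetic-data generator that plants
known trajectory archetypes, promoter motifs and annotation enrichments so
that every stage can be benchmarked against ground truth without any
external download.

## Differential expression

**Normalization.** Between-sample scaling uses TMM (trimmed mean of
M-values) factors via edgeR's implementation: reference sample by the
upper-quartile rule, 30%/5% two-sided trims on M and A, precision-weighted
mean, factors centred so their product is 1. TMM assumes most genes are not
differentially expressed; with strongly asymmetric regulation (a large
one-directional DE fraction) any trimmed-mean normalization leaves a
residual compositional bias, which is worth keeping in mind when
interpreting fold changes at strongly responsive time points.

**The test.** Each non-baseline time point is contrasted against 0 h with a
per-gene negative-binomial GLM (log link, offset `log(lib_size ×
norm_factor)`). The NB variance is `mu + phi * mu^2`. Per-gene dispersions
`phi` are method-of-moments estimates from replicate variation on the
normalized scale, pooled over all time points, then shrunk 50/50 toward a
mean-binned trend (deciles of average expression). The likelihood-ratio
statistic for the group coefficient is referred to an `F(1, d)`
distribution with `d = (residual df of the variance estimate) / 0.5^2`;
the denominator df encodes how precisely the shrunk dispersion is known
(with the dispersion treated as known, `d = Inf` and the reference is the
usual chi-squared). This small-sample correction matters: with three
replicates per group a plain chi-squared reference is several-fold
anticonservative in the far tail, which inflates the empirical FDR among
declared DEGs; the F reference restores calibration (verified by the
null-simulation and FDR-control tests in the package suite) while keeping
power above 0.8 for 4-fold effects at `mu = 100`, `phi = 0.1`.

**Filtering.** A gene is a DEG at time t when it shows *more than* a
2-fold change (strictly `|log2FC| > 1`), `FDR < 0.01` and `p < 0.01`. Both
the raw-p and the FDR cuts are applied jointly, exactly as this classical
triple filter is usually stated, although the FDR cut almost always
implies the p cut. BH adjustment is per time point by default because DEG
selection and reporting are per time point; a single global adjustment is
available via `fdr_scope = "global"`. Genes with fewer than 10 total
counts across all samples are never tested (`p = NA`): this minimum-count
rule is standard practice and prevents degenerate GLM fits. A reader for
externally computed statistics tables (`read_stats_table()`) lets the same
filter be applied verbatim to published per-contrast statistics.

## Trajectory clustering

**Profiles.** The clustered objects are per-gene time profiles: the mean
of `log2(CPM + 1)` over the replicates of each time point (CPM on
TMM-effective library sizes). Replicate averaging is the default because
the profile of interest is the time trajectory, not replicate scatter;
per-sample profiles can be supplied instead.

**Z-scaling.** Each row is standardized to mean 0 and *sample* standard
deviation 1 (n − 1 denominator; whether to use the population sd is a
genuine free choice — the sample sd is used and documented). Zero-variance
rows carry no shape and are excluded, listed in the `excluded` attribute.

**k-means.** Euclidean k-means with k-means++ seeding, 25 restarts by
default, keeping the restart with the smallest within-cluster sum of
squares; restarts that end with an empty cluster are discarded and
replaced. Everything is driven by one user seed, so runs are exactly
reproducible — determinism was prioritized over emulating any particular
GUI tool's unspecified initialization.

**Cluster direction and ordering.** A cluster is *down* when its centroid's
excursion below the baseline (0 h) value exceeds its excursion above it,
and *up* otherwise (ties → up). The excursion is measured relative to the
baseline centroid value, not relative to 0: after z-scaling, a sustained
repression profile sits *high* at baseline and below the row mean
afterwards, so its largest deviation from 0 is the positive baseline point
and a 0-referenced rule would mislabel it as upregulated. Clusters are then
relabeled deterministically — down clusters first, ordered by trough time,
then up clusters by peak time, ties by size — which reproduces the familiar
"top = downregulated, bottom = upregulated, ordered by response time"
layout of time-course cluster figures and makes labels comparable across
runs.

**Gap statistic.** For each candidate k, `log W_k` of the data is compared
with its expectation over B reference datasets drawn uniformly over the
per-feature ranges (the simpler of the two published reference variants;
the PCA-rotated variant is not implemented). `s_k = sd_B(log W*_k) sqrt(1
+ 1/B)`, and the selected k is the smallest k with `gap(k) ≥ gap(k+1) −
s_{k+1}`. The default B is 50; the package's own benchmark sweeps use B =
20 with 500 trajectories, which is ample for a 6-dimensional z-space. The
within-cluster dispersion is the plain within-cluster sum of squares; note
that `cluster::clusGap`'s pairwise form equals half of it, a constant
log-offset that cancels from the gap.

**Markers.** Within each requested cluster (by default the upregulated
ones), genes with centroid correlation ≥ 0.8 are ranked by that
correlation, ties broken by the gene's maximal |log2FC|, and the top two
are returned; a cluster with no gene at the floor falls back to pure
correlation ranking and is flagged.

## Promoters and cis-elements

The promoter is the 1-kb window immediately 5′ of the translation start on
the gene's sense strand: for a plus-strand gene with CDS starting at s,
genomic interval `[s − 1000, s − 1]`; for a minus-strand gene with CDS
ending at e, `[e + 1, e + 1000]` reverse-complemented. Windows clipped at a
contig edge are flagged `truncated`. Where a gene has several transcripts,
the longest CDS defines the start codon (deterministic and documented).
Overlapping upstream gene bodies are *not* masked — a plain
coordinate-window extraction, as genome-arithmetic tools produce.
Coordinates are 1-based inclusive everywhere except the BED export, which
converts to 0-based half-open at the boundary.

The built-in dictionary holds the 15 classical plant cis-elements printed
with their TF families (GCC-box, DRE/CRT, DRE-like; Myc-related; G-box,
G-box-like, ABRE-like, ACTCAT, TGA; AtMyb1–4; W-box; CG-1). Two dictionary
choices were genuinely open and are documented rather than guessed
silently: the W-box shorthand "TTGAC/T" is read as the canonical TTGACY
(`TTGAC(C/T)`), with the alternative `TTGA(C/T)` available by editing the
motif table; and AtMyb1/AtMyb2 share one printed consensus, carried
verbatim as two named entries. Scanning is exact degenerate-consensus
matching (no position weights): every sliding-window start where each base
falls in the allowed set, on both strands by default (cis-elements are
generally orientation-tolerant; single-strand mode is a flag). An `N` in
the sequence never matches. Presence is deduplicated per gene before
enrichment testing.

## Enrichment

For each (cluster, category) pair the over-representation p-value is the
upper hypergeometric tail `P(X ≥ k)` with cluster size n, category size K
and universe size N, computed via `phyper`. The universe defaults to all
genes of the annotation input (genome-wide); a DEGs-only universe is one
flag away, since "the total number of genes" is genuinely ambiguous in this
kind of analysis, and the choice is recorded in the run manifest. Tests are
one-sided (over-representation only). Heatmap matrices report `−log10` of
the *raw* p, as enrichment heatmaps conventionally do, while BH-adjusted q
values (within each category class) are written alongside in the results
table. Genes annotated but absent from the universe are dropped from the
category, not silently added. No GO-graph ancestor propagation is
performed: the input map is taken as-is.

A note on testing uniformity: upper-tail hypergeometric p-values are
discrete and super-uniform under the null, so a two-sided KS test against
the uniform would reject on discreteness alone. The package's null-
calibration tests therefore apply the randomized-p transform `F(k) + U ·
pmf(k)`, which is exactly Uniform(0, 1) under the null, before the KS test.

## The synthetic-data generator

The generator is first-class, tested code and defines the study conditions
for all benchmarks:

* **Design**: time points {0, 0.5, 1, 3, 6, 12} h, 3 replicates — the
  standard PTI time-course layout.
* **Counts**: NB draws with mean `mu_g · 2^{delta_{a(g), t}} · s_j`,
  per-gene baselines log-normal around 100 counts, per-gene dispersions
  Gamma around 0.1 — typical bulk RNA-seq values. Library-size factors are
  log-uniform in [0.7, 1.4] so normalization is non-trivial.
* **Archetypes**: ten baseline-anchored log2 trajectories, four
  downregulated (including a transient "down at 3 h, recovered by 12 h"
  shape) and six upregulated with peaks at 0.5, 1, 3, 6 h, a 6-and-12 h
  plateau, and 12 h. The shapes were fixed once for mutual separation in
  z-space (minimum pairwise centroid distance ≈ 1.6 z-units against the
  default noise sd of 0.3), so planted structure is recoverable but not
  trivially so.
* **Genome**: uppercase-ACGT contigs tiled deterministically with
  non-overlapping gene models of random strand, so promoter windows never
  collide with neighboring gene bodies. Motifs are planted into promoters
  with archetype-dependent probability `o/(1 + o)` (odds `o = 0` → never,
  `Inf` → always), written on the gene's sense strand; every planted
  occurrence is recorded in the truth manifest, and the scanner is required
  to recover 100% of them.
* **Annotations**: per-(gene, term) Bernoulli background at rate
  `terms_per_gene / n_terms`, with designated (archetype, term) pairs at
  `fold_enrichment` times that rate; fold 1 reduces exactly to the
  background, which makes the null-uniformity property hold by
  construction.

What the generator deliberately does **not** emulate: read-level artifacts
(mapping, positional bias, isoforms), diurnal/circadian confounding of the
treatment response, correlated gene programs beyond the planted archetypes,
GC or length biases in promoters, and overlapping gene architecture.
Passing the planted-recovery benchmarks therefore demonstrates the
correctness and calibration of the machinery, not robustness to every
failure mode of real tissue RNA-seq — in real data the baseline-anchored
contrast cannot separate treatment response from time-of-day effects, and
the package makes no attempt to deconvolve them.

## Numerical and reproducibility choices

* One master seed drives every stochastic stage through per-stage derived
  seeds (stage-name hashed, kept below 2^31), so stages are independently
  reproducible and a full pipeline rerun is byte-identical apart from the
  manifest timestamp.
* z-scaling invariants are enforced to 1e-10; writer/reader pairs
  round-trip at 1e-12; the BH and hypergeometric implementations agree
  with definitional oracles to 1e-12 in the test suite.
* Degenerate inputs have defined behavior: constant profiles are excluded
  with a report, empty motif dictionaries yield zero-column presence
  tables, `terms_per_gene = 0` yields an empty map, identical group counts
  give `log2FC = 0, p = 1`, and single-replicate groups are rejected.
* Benchmark problem sizes are chosen to be decisive yet quick: 5,000 genes
  for calibration/power, 2,000 trajectories for cluster recovery, 20 seeds
  × 500 trajectories for the gap sweep, 1,000 random 200-bp sequences for
  scanner equivalence. These sizes give the statistical checks tight
  expected bands while keeping a full verification run in minutes.

## Known limitations

* The NB test is a deliberately simple, deterministic stand-in for
  full quasi-likelihood machinery; it is calibrated and well-powered on
  planted effects, but exact numerical parity with any specific published
  pipeline's statistics is not a goal — `read_stats_table()` exists
  precisely so published statistics can be filtered verbatim.
* TMM inherits the usual trimmed-mean assumption; strongly asymmetric
  regulation biases fold changes toward the majority direction.
* The gap statistic uses the uniform-over-ranges reference only.
* Motif scanning is consensus matching, not PWM scoring; no repeat
  masking or conservation filtering.
* Enrichment treats categories independently (no GO DAG structure) and
  tests over-representation only (depletion is a flag away via the lower
  tail being out of scope by default).
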