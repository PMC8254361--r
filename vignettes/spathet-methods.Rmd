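---
title: "Quantifying spatial tumor heterogeneity from single-cell copy-number data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial tumor heterogeneity from single-cell copy-number data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spathet)
```

## The problem

Multi-regional single-cell DNA sequencing of a tumor yields, per region, a
matrix of integer copy-number states over fixed genomic bins — one row per
cell. Two qualitative regimes matter for downstream interpretation: the
tumor's subclones may be *spatially segregated* (each region is dominated by
its own subclone) or *spatially intermixed* (every region samples the same
subclonal mixture). `spathet` quantifies where a dataset sits between these
regimes with a single statistic, the Spatial Heterogeneity score (SHscore),
and ships the simulation machinery used to validate that statistic under
controlled tumor-evolution scenarios.

## The score

Cells are treated as points described by their copy-number profiles and the
regional samples as a fixed clustering of those points. For a cell $p$ in
sample $S_p$:

$$a(p) = \frac{1}{|S_p| - 1} \sum_{q \in S_p,\, q \neq p} d(p, q), \qquad
  b(p) = \min_{k \neq p's\ block} \frac{1}{|S_k|} \sum_{q \in S_k} d(p, q),$$

$$sh(p) = \frac{b(p) - a(p)}{\max\{a(p),\, b(p)\}}, \qquad
  \mathrm{SHscore}(S_1, \ldots, S_n) = \frac{1}{|D|} \sum_{p \in D} sh(p),$$

with $D$ the pooled dataset. These are the silhouette quantities with sample
membership as the cluster labels; any silhouette implementation given the
same distances reproduces the score, which the test suite exploits as an
independent oracle.

Distances are Manhattan ($L_1$): $d(p,q) = \sum_{\text{bins}} |CN_p - CN_q|$.
In the thousands of dimensions typical of binned copy-number profiles, lower-
order norms discriminate near from far neighbours better than Euclidean
distance, and $L_1$ sums are exact for integer input. Scores are computed on
the full bin set; feature selection (`select_variable_features()`) is opt-in
upstream.

Conventions, fixed and tested:

* a cell alone in its block contributes $sh(p) = 0$ (standard silhouette
  convention for singletons);
* $a = b = 0$ (exact duplicates across blocks) also gives 0 — indifference,
  not an error;
* the minimum in $b(p)$ runs over the *other blocks of the partition* (for
  two blocks it is simply the mean distance to the other sample);
* multiplying every copy number by a positive constant leaves each $sh(p)$
  unchanged (a ratio of distances), so the score is caller-scale-agnostic;
  input values are used as given, fractional or integer, with no rounding.

A score near 1 indicates internally homogeneous, mutually segregated
samples; near 0, interchangeable (well-mixed) samples; clearly negative
values usually flag preprocessing or quality problems. Printed output
annotates the conventional reading threshold of 0.2 — segregation worth
following up above it, effective homogeneity below — but no computation is
ever gated on that threshold.

### Partition scan

With more than two samples the informative quantity is often not the
all-separate score but the best grouping: `sh_scan()` enumerates **all** set
partitions of the samples into at least two blocks ($B_n - 1$ of them,
generalising the four groupings of the three-sample case), evaluates each on
one shared distance matrix, and sorts them. Ties break toward fewer blocks,
then canonical name. Bell-number growth motivates the default cap of six
samples (202 partitions); `allow_large = TRUE` lifts it deliberately. The
distance matrix is materialised once, dense and exact — around 1.6 GB of
doubles at 20,000 pooled cells, which is the practical ceiling of this
implementation; beyond that, subsample cells before scanning.

## Preprocessing

Tumor-cell filtering follows two rules with these defaults:

* **Ploidy** — remove cells whose bin-length-weighted mean copy number lies
  in the closed interval $[1.6, 2.9]$: diploid and pseudo-diploid cells are
  uninformative about tumor CNA structure. Endpoints are inclusive.
* **MAD** — among the remaining cells, remove those whose profile median
  absolute deviation (raw, unscaled) strictly exceeds the 95th percentile of
  the survivors' MADs; such erratic profiles typically reflect amplification
  artifacts or ongoing DNA replication. A cell exactly at the percentile is
  kept. Percentiles interpolate linearly between order statistics
  (`quantile()` type 7).

Computing the MAD cutoff *after* ploidy filtering targets noisy tumor cells
rather than letting the diploid bulk set the threshold; `mad_on_all = TRUE`
flips to the pooled alternative since the choice is genuinely open.
Re-filtering an already-filtered matrix removes nothing through the ploidy
rule but can trim further cells because the MAD percentile is recomputed on
the reduced population — documented, and intentional. Missing values are
refused rather than imputed: caller output is expected to be complete.

Feature selection keeps the bins with the highest across-cell variance
(standard for CN matrices, monotone, and easy to reason about), preserving
genomic order with ties broken toward earlier coordinates. Bin coordinates
are 1-based inclusive on disk (the Ginkgo SegCopy convention) and 0-based
half-open in memory.

## The tumor-evolution simulator

The validation engine grows a binary cell-division tree from one diploid
cell; leaves are the sampled cells, internal nodes are extinct intermediate
states. Defaults, each overridable in `sim_config()`:

| parameter | default | meaning |
|---|---|---|
| `theta` | 2.5e6 bp | mean CNA event size, Exponential lengths |
| `gain_p` | 0.5 | Geometric parameter; mean gained (or lost) copies = 1/`gain_p` |
| `events_per_division` | 1 | Poisson event count per daughter edge |
| `loss_fraction` | 0.5 | probability an event is a deletion |
| `split_shape` | none | uniform (Yule) division order; Beta-split propensities optional |
| `genome` | `"reduced"` | 1 chromosome, 100 Mbp, 100 kb bins (1,000 bins) |

The `"hg"` genome profile (22 autosome-like chromosomes, ~2.9 Gbp, 500 kb
bins) is available when a realistic chromosome structure matters; the
reduced profile keeps test and experiment runtimes at desk scale. `theta`
defaults to the midpoint of the $[500, 5 \times 10^6]$ bp range explored by
the parameter-independence experiment; since the score is a ratio of
distances it is largely insensitive to this choice, which the experiment
verifies rather than assumes. Event starts are uniform on a length-weighted
chromosome; events crossing the chromosome end are truncated, so Exponential
means are honoured for `theta` much smaller than the chromosome. Copy number
is floored at 0 and a bin at 0 ignores gains: deleted DNA cannot
re-amplify. "The first $k$ generated cells" of the sampling scenarios are
the extant cells after $k - 1$ divisions, with nodes numbered in birth
order.

What the simulator deliberately does **not** model: whole-genome doubling,
breakage–fusion–bridge cycles, focal amplification hotspots, selection or
fitness differences, and — importantly — any measurement model (bin-level
noise, segmentation error, caller bias). Green simulation tests therefore
certify the score's behaviour under idealised clonal structure, not its
robustness to caller artifacts; the ploidy/MAD filters are the only line of
defence offered for the latter.

### Scenarios

* **hom** — label each leaf by which of the first five cells it descends
  from: early, complete spatial segregation of five subclones.
* **het** — shuffle leaves uniformly over five labels: complete intermixing.
  Expected score is near zero and slightly negative (with all blocks drawn
  from one population, the nearest other block is on average marginally
  closer than one's own because of the minimum over blocks).
* **early-met / late-met** — when the primary tree has generated 1/4 (or
  3/4) of its final cell count, one extant cell's state seeds an
  independently growing metastasis tree; both run to 500 leaves. The seed
  fraction is a parameter; 1/4 is the default for "early".
* **var** — draw `theta` ~ U[500, 5e6] and `gain_p` ~ U[0.1, 0.9], grow
  1,000 leaves, split at the root into two samples.
* **deep** — grow one large tree, track the subtrees of the first `k`
  cells, keep samples whose cardinality lies in the interquartile range of
  the founder counts, and relate pairwise SHscores to the edge distance
  between founders (the samples' MRCAs).

A property of the default event model worth knowing when reading hom-style
results: two founders created by the same division are separated by exactly
two edges, and with Poisson(1) events per edge both edges are empty with
probability $e^{-2} \approx 0.14$ — in which case two of the five "subclones"
are genomically identical clones. Founder-level divergence is therefore
highly variable across simulated trees, and the hom score distribution is
correspondingly wide, including occasional near-zero or negative trees. The
aggregate ordering (hom above het) is robust; the per-tree ordering is not
guaranteed.

## Experiment drivers and problem sizes

The `run_*()` drivers fix the desk-scale profile used throughout the tests
and the acceptance script, all on the reduced genome:

* `run_regional()` — 20 trees × 1,000 leaves, five samples; hom and het
  scored on one shared distance matrix per tree; two-sided Mann–Whitney U
  (exact for groups ≤ 20, normal approximation above — the unpaired
  Wilcoxon rank-sum test under either name).
* `run_metastasis()` — 20 early + 20 late pairs at 500 cells per sample.
* `run_var()` — 50 replicates; Pearson tests of score against `theta` and
  `gain_p`.
* `run_deep()` — one 10,000-leaf tree, first 20 founders, IQR-filtered,
  all retained pairs scored; Pearson test of score against MRCA edge
  distance. The depth comparison adds five 2,500-leaf trees (five-way hom
  scores) below and one 40,000-leaf tree with 80 founders (45 sampled
  pairs) above, keeping roughly 500 leaves per founder throughout.
* `run_downsampling()` — a fixed sample pair re-scored while one sample is
  randomly downsampled per fraction and draw.

Every report carries its per-replicate values, a summary recomputable from
them, the test statistics, the configuration and the seeds; identical seeds
give bitwise-identical reports.

## Numerical and implementation notes

* Pairwise $L_1$ distances are computed exactly in compiled code (no
  approximate nearest neighbours); `stats::dist` serves as the oracle in
  tests.
* The silhouette aggregation is vectorised via a block-indicator matrix
  product; singleton and $0/0$ cases are patched to 0 after the fact.
* PCA uses `stats::prcomp` (centered, unscaled); UMAP delegates to `uwot`
  with a fixed seed and single-threaded SGD for determinism.
* Hierarchical clustering and the aggregated heatmap reuse the same $L_1$
  distance matrix; "ward" maps to `hclust`'s `ward.D2`. With a
  non-Euclidean metric Ward linkage is a well-behaved heuristic rather than
  a variance decomposition — `average` and `complete` are exposed for
  purists.
* Clustering wrappers delegate to `stats::kmeans`, `stats::hclust`,
  `kernlab::specc` and `mclust::Mclust`; external metrics without an
  installed single-call implementation (V-measure, Fowlkes–Mallows, mutual
  information, Davies–Bouldin, Calinski–Harabasz) are computed from their
  textbook contingency/scatter definitions and verified against
  hand-computed values in the tests.

## Worked example

```{r example, eval = FALSE}
a <- read_cnv(system.file("extdata", "synthetic_sample_A.tsv",
                          package = "spathet"), sample = "A")
b <- read_cnv(system.file("extdata", "synthetic_sample_B.tsv",
                          package = "spathet"), sample = "B")
pooled <- cnv_aggregate(list(a, b))
shscore(pooled)
#> SHscore: 0.1101  (40 cells; partition: A vs B)
#>   < 0.2: subclones well-mixed or spatial differences negligible
```

The two bundled tables are simulated (filenames say so): the two root
subtrees of a single 40-leaf tree on a small two-chromosome genome, written
in SegCopy format.

## Known limitations

* No measurement noise model; see above for what simulation tests do and do
  not certify.
* The score weights cells, not samples: strongly unbalanced samples pull
  the mean toward the large sample's cells. This follows the plain-mean
  definition; reweight upstream (downsample) if sample-balanced behaviour
  is wanted.
* The dense distance matrix bounds pooled dataset size (~20k cells in 8 GB).
* Partition enumeration is exponential; the cap is a guardrail, not a
  performance fix.
* No significance testing of SHscores and no phylogenetic reconstruction —
  the score summarises divergence, it does not infer history.
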