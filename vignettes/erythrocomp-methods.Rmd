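---
title: "Methods: cohort comparison of erythroid progenitor single-cell profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort comparison of erythroid progenitor single-cell profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythrocomp)
```

# Scope and model

`erythrocomp` implements a cohort-comparison workflow for deep, plate-based
single-cell UMI profiles of early erythroid progenitors (BFU-E), of the kind
used to compare normal controls (NC) against Diamond–Blackfan anemia patients
who are untreated (UT), glucocorticoid-responsive (GCR) or non-responsive
(GCNR). The workflow is: quality control, highly-variable-gene selection,
PCA + shared-nearest-neighbor (SNN) graph clustering, the Ro/e
cluster-composition statistic, gene-set summation scores with Wilcoxon–Holm
group comparisons, cell-cycle phase scoring, per-gene differential
expression with Bonferroni and fold-change filters, pre-ranked gene-set
enrichment, and Fisher over-representation. A negative-binomial cohort
simulator with a ground-truth channel provides fully self-contained inputs,
so every stage has recovery tests.

# Quality control

Genes are kept when detected (UMI ≥ 1) in strictly more than 3 cells. Cells
are kept when their detected-gene count lies strictly above 1,000 and
strictly below 10,000; the upper bound removes suspected doublets. The
filters run genes-first and are idempotent. These boundary semantics are
deliberate and literal: a gene seen in exactly 3 cells is removed, a cell
with exactly 1,000 detected genes is removed, a cell with exactly 10,000 is
removed.

The scoring layer is `log2(UMI + 1)`. A pseudocount of 1 keeps zeros at 0,
so the summation score of an unexpressed gene set is exactly 0. This layer
is *not* depth-normalized: the summation score is defined on log2 UMIs
directly, which is meaningful here because plate-based deep sequencing
yields comparable per-cell depths. Depth normalization (scaling each cell to
the median total, then `log2(x+1)`) is applied only where ratios matter —
the differential-expression fold changes. Whether to score on a normalized
layer instead is exposed simply by passing `normalized_layer()` output to
the scoring functions.

# Clustering

Highly variable genes are selected by binned dispersion: genes are grouped
into 20 mean-expression bins and the dispersion (variance/mean) is z-scored
within each bin; either the top-n genes (422 for a single-group run, 1,168
for an integrated run) or all genes above a z cutoff are used. Cells are
embedded by PCA of the centered/scaled HVG submatrix (20 components by
default, each component's sign fixed by its largest loading), connected in a
Jaccard-weighted SNN graph (k = 20, prune 1/15), and partitioned by
multi-level (Louvain) modularity optimization at resolution 1.0. Labels are
size-ordered (`C0` largest). Single-cell clusters are reattached to the
nearest centroid.

A design note on alignment: the original workflow this models aligned
samples with canonical correlation analysis before clustering. Here group
differences are biological gene-program shifts, not technical batches, so a
joint PCA is used instead; the batch-control diagnostic (below) is the
guard that this is defensible. Re-implementing a CCA aligner would add
substantial machinery without changing any downstream statistic.

The batch-control check operationalizes the plate design in which 16 cells
from one designated NC donor are placed on every 96-well plate: for each
control cell we compute the fraction of its nearest control neighbors that
come from other plates, normalize by the perfect-mixing expectation, and
flag the run when the score falls below 0.5 (1 means perfectly mixed).

Louvain at resolution 1.0 can split large homogeneous clusters in the
integrated four-group cohort (a known resolution-limit behavior); recovered
clusters are therefore mapped to planted subpopulations by majority truth
label wherever a truth channel exists, and composition/score tables are
reported in those terms.

# Cluster composition: Ro/e

For the clusters × groups contingency table, the expected count of a
(cluster, group) cell is `row total × column total / grand total`, and
Ro/e = observed/expected. Ro/e > 1 is called an increased cluster in that
group, Ro/e < 1 decreased. Because the expectation comes from the pooled
margins, the expected-count-weighted mean of Ro/e across clusters is exactly
1 within every group.

The per-(cluster, group) test is a 1-df chi-square without continuity
correction on the 2×2 collapse (in/out of cluster × in/out of group); this
matches a display with one p value per bar. An omnibus clusters × groups
chi-square is also attached (`glance()`), since the collapse convention is a
choice rather than a mandate. Per-donor Ro/e replicates are computed against
the pooled cluster proportions and summarized with SEM for overplotting.

# Gene-set scores and comparisons

The per-cell score of a gene set is the sum of the log2-transformed UMIs of
its genes (intersected with the matrix; the fraction of set genes present is
recorded). The score is additive over disjoint sets and zero for empty
ones. The proliferation score is the same summation over a user-supplied
curated list; the packaged synthetic programs include a planted
`proliferation` set, and for real data the list is a replaceable GMT input
— results depend on that list.

Group comparisons are two-sided Wilcoxon rank-sum tests: exact when both
sides have at most 10 cells and the data are tie-free, otherwise the normal
approximation with mid-ranks and tie correction (no continuity correction).
Families for the Holm step-down correction are all comparisons of one gene
set within one cluster — mirroring the bracket structure of a per-panel
display; the family definition is configurable by subsetting the input.
Comparisons pool cells (one observation per cell) rather than per-donor
summaries, matching dot-per-cell displays.

# Cell-cycle scoring

Each phase score (S, G2/M) is the mean expression of the phase set minus
the mean of a control pool drawn per set gene (50 controls from the same
average-expression bin, 25 bins). Control matching makes the score
invariant to adding a constant to every gene, and robust to depth. The
phase call is: S if the S score is positive and exceeds the G2/M score;
G2/M if that score is positive and at least the S score; otherwise G1 —
the convention of the scoring tool family this follows.

# Differential expression and enrichment

`de_between()` tests each gene with the vectorized normal-approximation
rank-sum on the depth-normalized layer, after pre-screening to genes
detected in at least 10% of either side (the Bonferroni denominator is the
number of genes actually tested, recorded in the result). The average fold
change is computed on linearized depth-normalized expression with an
epsilon of 1 on both means — the convention of the tool generation this
emulates, since no formula is universal; both the epsilon and the screen
are arguments. Retention uses adjusted p < 0.05 together with
avg_FC ≥ 1.3 in either direction, with both boundaries handled literally
(p = 0.05 removed, FC = 1.3 retained). `find_markers()` is one-vs-rest
`de_between()` keeping positive-direction genes.

Pre-ranked GSEA uses the classic running-sum statistic: hits increment
proportionally to |statistic|^1 (normalized within the set), misses
decrement 1/(N − n_set), and ES is the signed extremum. The null permutes
gene labels (1,000 draws by default) because only a ranking is available at
this stage; NES divides ES by the mean |null ES| of matching sign, the
empirical p is computed within the matching-sign null, and FDR is
Benjamini–Hochberg within each sign stratum. The optimized ES uses the
piecewise-linear shortcut (extrema can only occur at or immediately before
a hit); the test suite pins it to a brute-force full running sum at 1e-12.
Over-representation is the one-sided hypergeometric tail with BH across
sets, replacing a web-service lookup with a local computation against a
caller-supplied universe and GMT.

# The synthetic cohort generator

The generator defines the study conditions; it is first-class, tested code.
Defaults:

* Four groups with post-QC sizes 426 (NC), 428 (UT), 276 (GCR), 262 (GCNR)
  — 1,392 cells — with 4 donors per group, 96-well plates, and 16
  batch-control cells per plate drawn from one designated NC donor. The
  controls are NC biology and are counted inside the NC group size; this is
  the only allocation under which the printed group sizes and the
  controls-per-plate design coexist.
* Five subpopulations with disjoint 60-gene marker blocks (translation/RP
  theme for C0, TF for C1, G2/M for C2, G1/S-replication for C3,
  GATA1/erythroid for C4) at +2.5 log2FC, plus a +0.8 ribosomal-protein
  boost in C0. NC proportions (0.32, 0.22, 0.14, 0.12, 0.20); UT shifts C3
  up (0.27) and C4 down (0.08); GCNR additionally depletes C2 (0.05); GCR
  sits between NC and UT. The marker-block gene lists of the modeled study
  are not published, so the programs are synthetic labels shipped as GMT.
* Counts are negative binomial (gamma-Poisson) with a single global
  dispersion of 0.3, around per-cell depths drawn log-normally with median
  122,477 total UMIs (sdlog 0.35). Gene abundances follow a log-normal
  multiset whose spread is solved numerically (integrating over the depth
  distribution and the subpopulation renormalization factors) so the
  expected mean detected genes per cell is 3,594.
* Cell-cycle structure: per-subpopulation phase proportions (C2 mostly
  G2/M, C3 mostly S, the self-renewing/erythroid-primed compartments mostly
  G1; patient-group C3 pushed further into S), with 80-gene S and G2/M
  programs boosted +1.1 log2FC in cells of the matching phase. Phase genes
  are assigned abundances from the 85th–97th percentile band — canonical
  cycle markers are well-expressed genes — so a planted twofold change is
  visible on the log2 scale; ribosomal-protein genes take the top
  quantiles. The marker/phase effect sizes were chosen together so that the
  five subpopulations dominate the embedding while phases remain separable:
  markedly stronger phase programs split clusters along the cycle axis, and
  markedly weaker ones are not recoverable from matched-control scores.
* Group program shifts: UT and GCNR elevate G1/S-transition, DNA
  replication, apoptosis and P53 sets (+0.8) in the affected clusters and
  proliferation (+0.5) in C3; GCR elevates type 1 interferon (+1.0) and
  lowers proliferation (−0.5) in C3 and ribosomal-protein expression
  (−0.4) everywhere.
* Spike-ins are tied to the QC thresholds by construction: low-quality
  cells are simulated at 800 expected total UMIs (detected genes are then
  bounded by total UMIs, hence below 1,000), and doublets are sums of two
  cells at a depth-inflation factor solved from the NB detection formula at
  the 1st percentile parent depth so detected genes exceed 10,000 with an
  8% margin even after gene filtering.
* Donor allocation within groups is uniform (per-donor counts are not
  published); plates are filled donor-contiguously, as plate-based library
  construction does.

Everything is reproducible byte-for-byte from the configuration seed.

What the generator does *not* emulate: ambient RNA, per-gene dispersions,
batch effects beyond plate labels, doublets formed by chance rather than by
construction, and any read-level artifacts. Passing recovery tests on these
cohorts therefore demonstrates the statistics and the pipeline plumbing,
not robustness to real-data artifacts.

# Numerical choices and degenerate inputs

* HVG ties are broken by gene identifier order; constant genes can never be
  selected. Fewer expressed genes than bins collapses to a single bin with
  a warning.
* PCA on a rank-deficient layer truncates components with a warning;
  identical cells give an all-zero embedding.
* Fully tied Wilcoxon data has zero rank-sum variance; the comparison
  reports p = 1.
* Ro/e is undefined when the expected count is 0; empty margins are dropped
  with a warning.
* GSEA sets overlapping the universe in fewer than 2 genes are skipped with
  a warning; an all-zero ranking statistic falls back to unweighted hits.
* Control bins smaller than the control count sample with replacement, with
  a message.
* Stage seeds are derived deterministically from one global seed, so any
  stage can be re-run in isolation.

# Problem sizes in the test suite

The suite exercises the generator at the default cohort scale (426-cell NC
cohorts and the 1,392-cell integrated cohort with 16,000 genes) for the
recovery and calibration checks, and at a reduced scale (two groups of
80–90 cells, 1,200 genes, shallower depth) for the pipeline plumbing tests;
composition-null calibration uses 250 label-only replicates, since the
test's behavior depends only on labels. These sizes keep the whole suite
in the order of a minute while leaving every statistic at its intended
operating point.

# Interface note

The package is driven from R: tabular results are tibbles, result objects
carry `tidy()`/`glance()`/`autoplot()` methods, and `run_pipeline()` /
`report_run()` orchestrate the full workflow into a directory of TSVs, a
JSON summary and a markdown report. No shell binary is shipped; an R
session (or a two-line Rscript around `run_pipeline()`) is the intended
entry point.

# Known limitations

* The Ro/e chi-square collapse convention (per-bar 2×2) is one of two
  defensible readings; the omnibus test is reported alongside.
* Gene-permutation GSEA nulls are narrower than phenotype-permutation
  nulls; NES/FDR should be read accordingly.
* The summation score grows with the number of set genes present; scores
  are comparable across groups for a fixed set, not across sets.
* Depth differences between groups are not modeled or corrected beyond the
  DE layer; with strongly depth-confounded groups the unnormalized scoring
  layer would require the normalized variant.
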