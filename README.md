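# erythrocomp

Cohort-comparison analysis of single-cell UMI profiles of erythroid
progenitors (BFU-E), for transcriptomics researchers studying how clinical
groups differ in subpopulation composition and gene-program activity — the
setting of Diamond–Blackfan anemia (DBA), where bone-marrow progenitors
from normal controls (NC) are compared with untreated (UT),
glucocorticoid-responsive (GCR) and glucocorticoid-non-responsive (GCNR)
patients.

The package implements the full analysis chain:

* **QC**: genes detected (UMI ≥ 1) in > 3 cells; cells with detected genes
  in the open interval (1,000, 10,000); `log2(UMI + 1)` scoring layer.
* **Clustering**: binned-dispersion HVG selection, PCA (20 components),
  Jaccard-weighted shared-nearest-neighbor graph, Louvain modularity at
  resolution 1.0, and a plate-design batch-control mixing diagnostic.
* **Composition**: the Ro/e statistic per (cluster, group),

  Ro/e = observed / expected,  expected = (cluster total × group total) / N,

  with a 1-df chi-square per cell of the table (2×2 collapse, no continuity
  correction) and an omnibus test; Ro/e > 1 is an increased cluster, < 1
  decreased. Per-donor replicates with SEM.
* **Gene-set scores**: per-cell sum of log2 UMIs over a set (apoptosis,
  P53, G1/S transition, DNA replication, type 1 interferon, proliferation,
  ribosomal proteins…), compared across groups by two-sided Wilcoxon
  rank-sum tests with Holm correction within each (set, cluster) panel.
* **Cell cycle**: S and G2/M scores against expression-matched control
  genes; phase call S / G2M / G1; phase fractions per cluster and group.
* **Differential expression**: per-gene Wilcoxon on a depth-normalized
  layer, Bonferroni over tested genes, retention at p_adj < 0.05 and
  avg_FC ≥ 1.3; one-vs-rest cluster markers.
* **Enrichment**: pre-ranked GSEA (running-sum ES, gene-permutation null,
  NES, sign-stratified FDR) and Fisher/hypergeometric over-representation.
* **Synthetic cohorts**: a negative-binomial (gamma-Poisson) generator that
  plants the full latent structure — five subpopulations, group shifts,
  cell-cycle programs, plate batch controls, QC spike-ins — with a ground
  truth channel, calibrated to the modeled cohort's printed descriptors
  (1,392 cells: 426/428/276/262 per group; median 122,477 UMIs and mean
  3,594 detected genes per cell).

## Worked example

```r
library(erythrocomp)

res <- run_pipeline(pipeline_config(seed = 42), "demo_run")
s <- res$summary
```

The run simulates the default four-group cohort, applies QC
(`1392` cells and `13297` genes retained), confirms plate batch-control
mixing (score `0.994`, pass), clusters (recovered clusters are relabeled by
their majority planted subpopulation), and computes every downstream table.
The composition table shows the planted direction of every shift:

```r
dplyr::filter(tidy(res$roe), cluster %in% c("C2","C3","C4"),
              group %in% c("NC","UT","GCNR"))
#>   cluster group observed expected   roe chisq        p     shift
#> 1      C2  GCNR       19     35.0 0.543 10.41 1.25e-03 decreased
#> 3      C2    UT       69     57.2 1.207  4.07 4.38e-02 increased
#> 4      C3  GCNR       79     58.2 1.358 11.82 5.85e-04 increased
#> 5      C3    NC       50     94.6 0.529 38.90 4.47e-10 decreased
#> 6      C3    UT      130     95.0 1.368 23.92 1.01e-06 increased
#> 8      C4    NC       77     53.9 1.430 16.40 5.14e-05 increased
#> 9      C4    UT       28     54.1 0.517 20.83 5.01e-06 decreased
```

C3 (the G1/S-replication subpopulation) is enriched and C4 (the
erythroid-primed subpopulation) depleted in patients, and C2 is depleted
specifically in GCNR — the erythroid-development block the statistic is
designed to expose. The score comparisons read the same way:

```r
dplyr::filter(res$comparisons, set %in% c("type1_ifn","proliferation"),
              cluster == "C3")
#>             set cluster group_a group_b n_a n_b statistic        p   p_holm
#> 1     type1_ifn      C3      NC      UT  50 130      3126 6.92e-01 6.92e-01
#> 2     type1_ifn      C3      UT     GCR 130  50       327 1.01e-20 3.02e-20
#> 4 proliferation      C3      NC      UT  50 130      2054 1.34e-04 1.34e-04
#> 5 proliferation      C3      UT     GCR 130  50      5105 3.14e-09 9.41e-09
```

The type 1 interferon program is elevated in GCR relative to UT (Holm
p ≈ 3e-20) while proliferation is lower in GCR — the glucocorticoid
response signature — and the Wilcoxon statistic `W` is the rank-sum of the
first group. `report_run("demo_run")` renders the tables to a single
markdown report; `autoplot(res$roe)`, `plot_embedding()`,
`plot_score_beeswarm()` and `plot_phase_fractions()` draw the standard
figures.

Individual stages compose with the pipe, e.g.:

```r
cohort <- simulate_cohort(synth_config(seed = 1))
qc     <- apply_qc(cohort$counts)
layer  <- log2_layer(qc$counts)
layer |>
  geneset_score(cohort$gene_sets$apoptosis, "apoptosis") |>
  dplyr::left_join(cohort$annotations, by = "cell") |>
  compare_scores(list(c("NC", "UT")))
```

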