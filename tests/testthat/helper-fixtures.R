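# Shared fixtures and independent mini-oracles. Expensive cohorts are
# generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small, fast cohort: 2 groups, shallow depth, few genes.
small_config <- function(...) {
  synth_config(
    groups = c("NC", "UT"),
    group_sizes = c(NC = 80, UT = 80),
    n_genes = 1200,
    donors_per_group = 2,
    depth_lognormal = c(meanlog = log(20000), sdlog = 0.3),
    mean_detected_target = 600,
    doublet_min_genes = 1000,
    plate_size = 48,
    controls_per_plate = 8,
    ...
  )
}

small_cohort <- function() {
  cached("small_cohort", simulate_cohort(small_config(seed = 101)))
}

# Default-condition NC cohort at a given seed (used by several recovery
# checks); cached per seed.
nc_cohort <- function(seed) {
  cached(paste0("nc_cohort_", seed),
         simulate_cohort(synth_config(groups = "NC", seed = seed)))
}

# Default-condition full four-group cohort.
full_cohort <- function() {
  cached("full_cohort", simulate_cohort(synth_config(seed = 20260927 %% 1000)))
}

# Clustered view of the full cohort (QC, log2 layer, HVGs, PCA, SNN-Louvain)
# with recovered clusters relabeled by majority planted subpopulation.
full_analysis <- function() {
  cached("full_analysis", {
    co <- full_cohort()
    qc <- apply_qc(co$counts)
    layer <- log2_layer(qc$counts)
    emb <- reduce_dims(layer, select_hvgs(layer, target_n = 1168), 20)
    cl <- cluster_graph(emb, k = 20, resolution = 1, seed = 7)
    truth <- co$truth[match(cl$cell, co$truth$cell), ]
    map <- majority_map(cl$cluster, truth$subpop)
    cl$label <- unname(map[as.character(cl$cluster)])
    ann <- co$annotations[match(cl$cell, co$annotations$cell), ]
    list(cohort = co, qc = qc, layer = layer, emb = emb, clusters = cl,
         truth = truth, ann = ann,
         cells = cbind(cl, group = ann$group, donor = ann$donor))
  })
}

majority_map <- function(clusters, truth_labels) {
  keep <- !is.na(truth_labels)
  tab <- table(clusters[keep], truth_labels[keep])
  setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  si <- s(tab); sr <- s(rowSums(tab)); sc <- s(colSums(tab)); st <- s(sum(tab))
  (si - sr * sc / st) / ((sr + sc) / 2 - sr * sc / st)
}

# Enumeration oracle for the exact two-sided Wilcoxon rank-sum p value:
# every C(n+m, n) assignment of the pooled ranks to side A.
oracle_wilcox_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx])) - n * (n + 1) / 2
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Brute-force GSEA enrichment score: the full N-step running sum.
oracle_gsea_es <- function(stat_sorted, hit_pos, weight = 1) {
  N <- length(stat_sorted)
  m <- length(hit_pos)
  w <- abs(stat_sorted[hit_pos])^weight
  if (sum(w) == 0) w <- rep(1, m)
  w <- w / sum(w)
  inc <- numeric(N)
  inc[hit_pos] <- w
  miss <- rep(1 / (N - m), N)
  miss[hit_pos] <- 0
  run <- cumsum(inc - miss)
  run[which.max(abs(run))]
}

# Holm step-down applied by hand (independent of stats::p.adjust).
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}
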