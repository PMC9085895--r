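# Differential expression between cell groups and cluster markers.
#
# Per-gene two-sided Wilcoxon rank-sum on the depth-normalized log layer,
# Bonferroni correction over the genes actually tested, and the study's
# retention rule: adjusted p < 0.05 together with an average fold change of
# at least 1.3 in either direction. avg_fc is computed on linearized
# depth-normalized expression with an epsilon of 1 on both means.

#' Differential expression between two cell sets
#'
#' @param layer Dense cells x genes depth-normalized log2 layer (see
#'   [normalized_layer()]).
#' @param cells_a,cells_b Cell identifiers (rownames of `layer`) of the two
#'   sides; each side needs at least 3 cells.
#' @param min_pct Pre-screen: only genes detected (layer > 0) in at least
#'   this fraction of either side are tested (default 0.1). The Bonferroni
#'   correction runs over the genes tested.
#' @param eps Smoothing constant added to both linearized means in the fold
#'   change (default 1).
#' @return A tibble of class `de_table`, one row per tested gene: `gene`,
#'   `avg_fc` (ratio scale, side A over side B), `log2_fc`, `statistic`,
#'   `p_raw`, `p_adj`, `pct_a`, `pct_b`, `direction` (`"up"` in A or
#'   `"down"`). Attribute `n_tested` records the Bonferroni denominator.
#' @export
de_between <- function(layer, cells_a, cells_b, min_pct = 0.1, eps = 1) {
  idx_a <- match(cells_a, rownames(layer))
  idx_b <- match(cells_b, rownames(layer))
  if (anyNA(idx_a) || anyNA(idx_b)) abort("Unknown cell identifiers.")
  if (length(idx_a) < 3 || length(idx_b) < 3) {
    abort("Each side needs at least 3 cells.")
  }
  pct_a <- colMeans(layer[idx_a, , drop = FALSE] > 0)
  pct_b <- colMeans(layer[idx_b, , drop = FALSE] > 0)
  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  if (!length(tested)) {
    out <- tibble(gene = character(), avg_fc = numeric(), log2_fc = numeric(),
                  statistic = numeric(), p_raw = numeric(), p_adj = numeric(),
                  pct_a = numeric(), pct_b = numeric(), direction = character())
    attr(out, "n_tested") <- 0L
    class(out) <- c("de_table", class(out))
    return(out)
  }
  sub <- layer[, tested, drop = FALSE]
  wt <- rank_sum_matrix(sub, idx_a, idx_b)
  lin <- 2^sub - 1  # back to linear depth-normalized expression
  mean_a <- colMeans(lin[idx_a, , drop = FALSE])
  mean_b <- colMeans(lin[idx_b, , drop = FALSE])
  avg_fc <- (mean_a + eps) / (mean_b + eps)
  out <- tibble(
    gene = colnames(sub),
    avg_fc = unname(avg_fc),
    log2_fc = log2(unname(avg_fc)),
    statistic = wt$stat,
    p_raw = wt$p,
    p_adj = pmin(1, wt$p * length(tested)),
    pct_a = unname(pct_a[tested]),
    pct_b = unname(pct_b[tested]),
    direction = ifelse(avg_fc >= 1, "up", "down")
  )
  attr(out, "n_tested") <- length(tested)
  class(out) <- c("de_table", class(out))
  out
}

#' Apply the DEG retention thresholds
#'
#' Retains genes with adjusted p strictly below `p_cutoff` and an average
#' fold change of at least `fc_cutoff` in either direction (`avg_fc >= 1.3`
#' or `avg_fc <= 1/1.3` at the defaults). Both boundaries follow the stated
#' rule exactly: `p_adj = 0.05` is removed, `avg_fc = 1.3` is retained.
#'
#' @param de A [de_between()] result.
#' @param p_cutoff Adjusted-p threshold, exclusive (default 0.05).
#' @param fc_cutoff Fold-change threshold, inclusive (default 1.3).
#' @return The filtered `de_table`.
#' @export
filter_degs <- function(de, p_cutoff = 0.05, fc_cutoff = 1.3) {
  keep <- de$p_adj < p_cutoff &
    (de$avg_fc >= fc_cutoff | de$avg_fc <= 1 / fc_cutoff)
  out <- de[keep, , drop = FALSE]
  attr(out, "n_tested") <- attr(de, "n_tested")
  class(out) <- unique(c("de_table", class(out)))
  out
}

#' One-vs-rest cluster markers
#'
#' Runs [de_between()] for each cluster against all other cells and keeps
#' positive-direction genes (higher in the cluster). Clusters with fewer
#' than 3 cells are skipped with a message.
#'
#' @param layer Dense cells x genes depth-normalized log2 layer.
#' @param clusters A data frame with `cell` and `cluster` columns.
#' @param top_n Markers retained per cluster in the `top` element
#'   (default 10).
#' @param ... Passed to [de_between()].
#' @return A list with `tables` (named list of full per-cluster `de_table`s,
#'   positive direction only, ordered by adjusted p then fold change) and
#'   `top` (a single tibble of the top `top_n` markers per cluster).
#' @export
find_markers <- function(layer, clusters, top_n = 10, ...) {
  cl <- split(clusters$cell, clusters$cluster)
  cl <- cl[lengths(cl) > 0]
  if (length(cl) < 2) abort("Need at least 2 clusters.")
  tables <- list()
  for (nm in names(cl)) {
    if (length(cl[[nm]]) < 3) {
      inform(sprintf("Skipping cluster %s: fewer than 3 cells.", nm))
      next
    }
    rest <- setdiff(rownames(layer), cl[[nm]])
    de <- de_between(layer, cl[[nm]], rest, ...)
    de <- de[de$avg_fc > 1, , drop = FALSE]
    tables[[nm]] <- de[order(de$p_adj, -de$avg_fc), ]
  }
  top <- list_rbind(imap(tables, function(tb, nm) {
    bind_cols(cluster = rep(nm, min(top_n, nrow(tb))), head(tb, top_n))
  }))
  list(tables = tables, top = top)
}
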