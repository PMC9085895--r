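# Subpopulation recovery: HVG selection, PCA, SNN graph, modularity
# clustering, and the batch-control mixing diagnostic.
#
# Alignment note: group differences in this pipeline are biological gene
# programs rather than technical batches, so a joint PCA over all cells
# replaces the original CCA subspace alignment; per-group centering is
# available as a robustness switch.

#' Select highly variable genes by binned dispersion
#'
#' Genes are binned by mean expression; within each bin the dispersion
#' (variance/mean) is z-scored, and genes are ranked by that z-score. Either
#' the top `target_n` genes or all genes above `z_cutoff` are returned. Ties
#' are broken by gene identifier order, so the selection is deterministic.
#'
#' @param layer Dense cells x genes log2 expression layer (see
#'   [log2_layer()]).
#' @param target_n Number of genes to return (e.g. 422 for a single-group
#'   run, 1168 for an integrated run). Ignored when `NULL`.
#' @param z_cutoff Dispersion z-score cutoff used when `target_n` is `NULL`
#'   (default 1).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return Character vector of selected gene names, ordered by decreasing
#'   dispersion z-score.
#' @export
select_hvgs <- function(layer, target_n = NULL, z_cutoff = 1, n_bins = 20) {
  if (nrow(layer) < 2) abort("HVG selection needs at least 2 cells.")
  mu <- colMeans(layer)
  v <- apply(layer, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  usable <- mu > 0 & is.finite(disp)
  if (sum(usable) < n_bins) {
    warn("Fewer expressed genes than bins; using a single bin.")
    n_bins <- 1
  }
  bins <- rep(1L, length(mu))
  if (n_bins > 1) {
    brk <- unique(quantile(mu[usable], probs = seq(0, 1, length.out = n_bins + 1)))
    bins[usable] <- as.integer(cut(mu[usable], breaks = brk, include.lowest = TRUE))
  }
  z <- rep(-Inf, length(mu))
  for (b in unique(bins[usable])) {
    idx <- which(usable & bins == b)
    s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  # constant genes (zero variance) can never be selected
  z[v == 0] <- -Inf
  ord <- order(-z, colnames(layer))
  if (!is.null(target_n)) {
    target_n <- min(target_n, sum(is.finite(z)))
    colnames(layer)[ord[seq_len(target_n)]]
  } else {
    sel <- ord[z[ord] > z_cutoff]
    colnames(layer)[sel]
  }
}

#' Principal-component embedding of the HVG layer
#'
#' Centers and scales each selected gene, then projects cells onto the top
#' principal axes. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param layer Dense cells x genes expression layer.
#' @param hvgs Character vector of genes to use.
#' @param n_components Number of components to keep (default 20).
#' @return A cells x components numeric matrix (rownames = cell ids).
#' @export
reduce_dims <- function(layer, hvgs, n_components = 20) {
  hvgs <- intersect(hvgs, colnames(layer))
  if (!length(hvgs)) abort("No HVGs present in the expression layer.")
  x <- layer[, hvgs, drop = FALSE]
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!any(keep)) {
    # no variable gene at all (e.g. identical cells): degenerate flat embedding
    emb <- matrix(0, nrow(layer), n_components,
                  dimnames = list(rownames(layer),
                                  paste0("PC", seq_len(n_components))))
    return(emb)
  }
  x <- scale(x[, keep, drop = FALSE])
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warn(sprintf("n_components reduced from %d to matrix rank %d.",
                 n_components, max_rank))
    n_components <- max_rank
  }
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  emb <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(emb))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- rownames(layer)
  emb
}

# Jaccard-weighted shared-nearest-neighbor graph from an embedding.
.snn_graph <- function(embedding, k, prune = 1 / 15) {
  n <- nrow(embedding)
  d <- as.matrix(dist(embedding))
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    nbr[i, ] <- order(d[i, ])[2:(k + 1)]
  }
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(nbr)),
    x = 1, dims = c(n, n)
  )
  diag(inc) <- 1  # a cell shares itself with its neighbors
  shared <- methods::as(methods::as(Matrix::tcrossprod(inc), "generalMatrix"),
                        "TsparseMatrix")
  w <- shared@x / (2 * (k + 1) - shared@x)  # Jaccard on neighbor sets
  keep <- w >= prune & shared@i != shared@j
  Matrix::sparseMatrix(i = shared@i[keep] + 1L, j = shared@j[keep] + 1L,
                       x = w[keep], dims = c(n, n))
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a Jaccard-weighted SNN graph from the embedding and partitions it
#' by multi-level modularity (Louvain) optimization at the given resolution.
#' Cluster labels are `C0, C1, ...` ordered by decreasing size. Any
#' single-cell cluster is reassigned to the cluster with the nearest
#' centroid.
#'
#' @param embedding Cells x components matrix from [reduce_dims()].
#' @param k Number of nearest neighbors (default 20).
#' @param resolution Modularity resolution (default 1.0, the value used for
#'   the modeled cohort).
#' @param seed Integer seed for the (stochastic) modularity optimizer.
#' @return A tibble with `cell`, `cluster` (factor, size-ordered) plus a
#'   `modularity` attribute.
#' @export
cluster_graph <- function(embedding, k = 20, resolution = 1.0, seed = 1L) {
  n <- nrow(embedding)
  if (n < k + 1) abort("Need at least k + 1 cells to build a k-NN graph.")
  adj <- .snn_graph(embedding, k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  # singletons: attach to nearest cluster centroid
  sizes <- table(memb)
  singles <- names(sizes)[sizes == 1]
  if (length(singles)) {
    inform(sprintf("Reassigning %d singleton cluster(s) by centroid distance.",
                   length(singles)))
    big <- setdiff(names(sizes), singles)
    cent <- do.call(rbind, lapply(big, function(cl) {
      colMeans(embedding[memb == as.integer(cl), , drop = FALSE])
    }))
    for (cl in singles) {
      i <- which(memb == as.integer(cl))
      dd <- sqrt(rowSums((cent - matrix(embedding[i, ], nrow(cent),
                                        ncol(cent), byrow = TRUE))^2))
      memb[i] <- as.integer(big[which.min(dd)])
    }
  }
  # relabel by decreasing size
  ord <- names(sort(table(memb), decreasing = TRUE))
  relab <- setNames(paste0("C", seq_along(ord) - 1L), ord)
  labels <- factor(unname(relab[as.character(memb)]),
                   levels = paste0("C", seq_along(ord) - 1L))
  out <- tibble(cell = rownames(embedding), cluster = labels)
  attr(out, "modularity") <- igraph::modularity(g, memb,
                                                weights = igraph::E(g)$weight)
  out
}

#' Batch-control mixing diagnostic
#'
#' For each batch-control cell, the fraction of its k nearest control
#' neighbors (in the embedding) that come from other plates is compared with
#' the expectation under perfect mixing; the score is the ratio of the two
#' (1 = perfectly mixed, 0 = fully plate-separated). The run passes when the
#' score is at least `threshold`.
#'
#' @param embedding Cells x components matrix.
#' @param is_control Logical vector flagging batch-control cells.
#' @param plate Plate identifier per cell.
#' @param k Neighbors per control cell (default 10, capped at the number of
#'   other controls).
#' @param threshold Pass threshold (default 0.5).
#' @return A list with `score`, `pass`, `n_controls`, `n_plates`.
#' @export
batch_control_check <- function(embedding, is_control, plate, k = 10,
                                threshold = 0.5) {
  ctrl <- which(is_control)
  if (!length(ctrl)) abort("No batch-control cells flagged.")
  plates <- plate[ctrl]
  if (length(unique(plates)) < 2) {
    abort("Batch-control check needs controls on at least 2 plates.")
  }
  emb <- embedding[ctrl, , drop = FALSE]
  n <- length(ctrl)
  k <- min(k, n - 1)
  d <- as.matrix(dist(emb))
  obs <- numeric(n)
  exp_frac <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    obs[i] <- mean(plates[nb] != plates[i])
    exp_frac[i] <- sum(plates != plates[i]) / (n - 1)
  }
  score <- mean(obs) / mean(exp_frac)
  list(score = score, pass = score >= threshold,
       n_controls = n, n_plates = length(unique(plates)))
}
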