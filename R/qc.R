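# Quality control and the log2 expression layer.
#
# Filter semantics follow the study's stated criteria literally: genes are
# kept when detected (UMI >= 1) in strictly more than `min_cells` cells;
# cells are kept when their detected-gene count is strictly greater than
# `min_genes` and strictly below `max_genes` (cells at >= `max_genes` are
# treated as likely doublets).

#' QC parameters
#'
#' @param min_cells_per_gene Genes must be detected in strictly more than
#'   this many cells (default 3).
#' @param min_genes_per_cell Cells must have strictly more detected genes
#'   than this (default 1000).
#' @param max_genes_per_cell Cells with at least this many detected genes are
#'   excluded as suspected doublets (default 10000).
#' @param pseudocount Pseudocount for the log2 layer (default 1).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_cells_per_gene = 3L, min_genes_per_cell = 1000L,
                      max_genes_per_cell = 10000L, pseudocount = 1) {
  if (min_genes_per_cell >= max_genes_per_cell) {
    abort("min_genes_per_cell must be below max_genes_per_cell.")
  }
  if (pseudocount < 0) abort("pseudocount must be non-negative.")
  structure(list(
    min_cells_per_gene = min_cells_per_gene,
    min_genes_per_cell = min_genes_per_cell,
    max_genes_per_cell = max_genes_per_cell,
    pseudocount = pseudocount
  ), class = "qc_params")
}

#' Per-cell totals and detected-gene counts
#'
#' @param counts Sparse or dense cells x genes UMI count matrix.
#' @return A tibble with one row per cell: `cell`, `total_umi`,
#'   `detected_genes`.
#' @export
cell_stats <- function(counts) {
  counts <- as_umi_matrix(counts)
  tibble(
    cell = rownames(counts),
    total_umi = unname(Matrix::rowSums(counts)),
    detected_genes = unname(Matrix::rowSums(counts >= 1))
  )
}

#' Filter genes by detection frequency
#'
#' Keeps genes detected (UMI >= 1) in strictly more than
#' `params$min_cells_per_gene` cells. A gene seen in exactly that many cells
#' is removed.
#'
#' @param counts Cells x genes UMI count matrix.
#' @param params A [qc_params()] object.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, params = qc_params()) {
  counts <- stopifnot_counts(as_umi_matrix(counts))
  if (nrow(counts) == 0 || ncol(counts) == 0) return(counts)
  n_cells_detected <- Matrix::colSums(counts >= 1)
  counts[, n_cells_detected > params$min_cells_per_gene, drop = FALSE]
}

#' Filter cells by detected-gene count
#'
#' Keeps cells whose detected-gene count lies strictly above
#' `min_genes_per_cell` and strictly below `max_genes_per_cell`; cells at or
#' above the upper bound are removed as suspected doublets.
#'
#' @inheritParams filter_genes
#' @return A list with `counts` (filtered matrix) and `report`, a tibble of
#'   class `qc_report` with one row per input cell: `cell`,
#'   `detected_genes`, `kept` and `reason` (`NA`, `"too_few_genes"` or
#'   `"too_many_genes"`).
#' @export
filter_cells <- function(counts, params = qc_params()) {
  counts <- stopifnot_counts(as_umi_matrix(counts))
  detected <- Matrix::rowSums(counts >= 1)
  too_few <- detected <= params$min_genes_per_cell
  too_many <- detected >= params$max_genes_per_cell
  keep <- !too_few & !too_many
  report <- tibble(
    cell = rownames(counts),
    detected_genes = as.numeric(detected),
    kept = keep,
    reason = dplyr::case_when(
      too_few ~ "too_few_genes",
      too_many ~ "too_many_genes",
      TRUE ~ NA_character_
    )
  )
  attr(report, "n_cells_in") <- nrow(counts)
  attr(report, "n_cells_out") <- sum(keep)
  class(report) <- c("qc_report", class(report))
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Run the full QC stage
#'
#' Applies the gene filter, then the cell filter, in that order.
#'
#' @inheritParams filter_genes
#' @return A list with `counts` and `report` (see [filter_cells()]).
#' @export
apply_qc <- function(counts, params = qc_params()) {
  filter_cells(filter_genes(counts, params), params)
}

#' Log2 expression layer
#'
#' Entrywise `log2(count + pseudocount)`. With the default pseudocount of 1,
#' zeros stay at 0 and the per-cell gene-set summation score of an
#' unexpressed set is 0. This layer is deliberately not depth-normalized:
#' the summation score operates on log2-transformed UMIs directly. A
#' depth-normalized layer for fold changes is provided by
#' [normalized_layer()].
#'
#' @param counts Cells x genes UMI count matrix.
#' @param pseudocount Non-negative pseudocount (default 1). Zero is an error
#'   when zero counts are present (log of zero is undefined).
#' @return A dense cells x genes matrix of log2 expression values.
#' @export
log2_layer <- function(counts, pseudocount = 1) {
  counts <- as_umi_matrix(counts)
  if (pseudocount < 0) abort("pseudocount must be non-negative.")
  if (pseudocount == 0 && any(Matrix::rowSums(counts >= 1) < ncol(counts))) {
    abort("pseudocount = 0 is undefined in the presence of zero counts.")
  }
  m <- as.matrix(counts)
  log2(m + pseudocount)
}

#' Depth-normalized log2 layer
#'
#' Counts are scaled so every cell has the median total depth, then
#' log2(x + 1) transformed. Used for differential-expression fold changes;
#' gene-set scores use the unnormalized [log2_layer()].
#'
#' @param counts Cells x genes UMI count matrix.
#' @return A dense cells x genes matrix.
#' @export
normalized_layer <- function(counts) {
  counts <- as_umi_matrix(counts)
  totals <- Matrix::rowSums(counts)
  target <- median(totals[totals > 0])
  scale_f <- ifelse(totals > 0, target / totals, 0)
  m <- as.matrix(counts) * scale_f
  log2(m + 1)
}
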