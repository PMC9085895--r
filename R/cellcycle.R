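# Cell-cycle phase scoring and assignment.
#
# Each phase score is the mean expression of the phase's gene set minus the
# mean expression of a control pool drawn, per set gene, from the same
# average-expression bin. Subtracting expression-matched controls makes the
# score robust to per-cell depth and to any constant offset. A cell is
# called S when its S score is positive and exceeds the G2/M score, G2/M
# when that score is positive and at least the S score, and G1 otherwise.

#' Cell-cycle phase scores
#'
#' @param layer Dense cells x genes log2 expression layer.
#' @param s_genes,g2m_genes Gene sets for the S and G2/M programs.
#' @param n_bins Number of average-expression bins for control matching
#'   (default 25).
#' @param n_ctrl Control genes drawn per set gene (default 50); bins with
#'   fewer genes are sampled with replacement (with a message).
#' @param seed Integer seed for control sampling.
#' @return A tibble of class `phase_scores` with `cell`, `s_score`,
#'   `g2m_score`, `phase`.
#' @export
cellcycle_scores <- function(layer, s_genes, g2m_genes, n_bins = 25,
                             n_ctrl = 50, seed = 1L) {
  s_genes <- intersect(s_genes, colnames(layer))
  g2m_genes <- intersect(g2m_genes, colnames(layer))
  if (!length(s_genes) || !length(g2m_genes)) {
    abort("Both phase gene sets must overlap the expression matrix.")
  }
  avg <- colMeans(layer)
  brk <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- as.integer(cut(avg, breaks = brk, include.lowest = TRUE))
  names(bins) <- colnames(layer)

  one_score <- function(set_genes) {
    ctrl <- character(0)
    for (g in set_genes) {
      pool <- setdiff(names(bins)[bins == bins[[g]]], set_genes)
      if (!length(pool)) pool <- setdiff(names(bins), set_genes)
      if (length(pool) < n_ctrl) {
        inform("Control bin smaller than n_ctrl; sampling with replacement.")
        ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
      } else {
        ctrl <- c(ctrl, sample(pool, n_ctrl))
      }
    }
    rowMeans(layer[, set_genes, drop = FALSE]) -
      rowMeans(layer[, ctrl, drop = FALSE])
  }

  with_seed(seed, {
    s_score <- one_score(s_genes)
    g2m_score <- one_score(g2m_genes)
    out <- tibble(
      cell = rownames(layer),
      s_score = unname(s_score),
      g2m_score = unname(g2m_score)
    )
    out$phase <- assign_phase(out)
    class(out) <- c("phase_scores", class(out))
    out
  })
}

#' Assign cell-cycle phases from phase scores
#'
#' `S` when `s_score > g2m_score` and `s_score > 0`; `G2M` when
#' `g2m_score >= s_score` and `g2m_score > 0`; otherwise `G1`.
#'
#' @param scores A data frame with `s_score` and `g2m_score` columns.
#' @return A character vector of phases (`"G1"`, `"S"`, `"G2M"`).
#' @export
assign_phase <- function(scores) {
  dplyr::case_when(
    scores$s_score > scores$g2m_score & scores$s_score > 0 ~ "S",
    scores$g2m_score >= scores$s_score & scores$g2m_score > 0 ~ "G2M",
    TRUE ~ "G1"
  )
}

#' Phase fractions per cluster and group
#'
#' @param data A data frame with one row per cell holding `phase` plus the
#'   grouping columns.
#' @param cluster,group Column names of the stratifying labels; either may
#'   be `NULL` to pool.
#' @param phase Column name of the phase labels (default `"phase"`).
#' @return A tibble with the grouping columns, `phase`, `n` and `fraction`;
#'   fractions sum to 1 within each stratum.
#' @export
phase_fractions <- function(data, cluster = "cluster", group = "group",
                            phase = "phase") {
  keys <- c(cluster, group)
  keys <- keys[!vapply(keys, is.null, logical(1))]
  keys <- intersect(unlist(keys), names(data))
  counts <- data |>
    mutate(phase = factor(.data[[phase]], levels = c("G1", "S", "G2M"))) |>
    group_by(across(dplyr::all_of(keys)), .data$phase, .drop = FALSE) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  counts
}
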