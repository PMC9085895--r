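# Diagnostic plots for the main result types.

#' Embedding scatter plot
#'
#' @param embedding Cells x components matrix from [reduce_dims()].
#' @param labels Optional per-cell labels (cluster, group, ...).
#' @param dims Which two components to draw (default 1:2).
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels = NULL, dims = c(1, 2)) {
  df <- tibble(
    x = embedding[, dims[1]],
    y = embedding[, dims[2]],
    label = if (is.null(labels)) "cells" else as.character(labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ro/e bar plot
#'
#' Bars show Ro/e per (cluster, group); the dashed line marks Ro/e = 1
#' (observed = expected). Optional per-donor points overlay replicates.
#'
#' @param object A [roe_table()] result.
#' @param by_donor Optional `by_donor` tibble from [roe_per_donor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roe_result <- function(object, by_donor = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$group, .data$roe, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(y = "Ro/e", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(by_donor)) {
    p <- p + ggplot2::geom_jitter(
      data = by_donor, ggplot2::aes(.data$group, .data$roe),
      inherit.aes = FALSE, width = 0.15, size = 1
    )
  }
  p
}

#' Gene-set score beeswarm-style plot
#'
#' Jittered per-cell scores by group, optionally faceted by cluster.
#'
#' @param scores Tibble from [score_genesets()] joined with `group` (and
#'   optionally `cluster`).
#' @param set Gene-set name to draw.
#' @return A ggplot object.
#' @export
plot_score_beeswarm <- function(scores, set) {
  df <- scores[scores$set == set, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$score,
                                        colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.25, size = 0.6, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "black") +
    ggplot2::labs(title = set, x = NULL, y = "gene-set score (sum log2 UMI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if ("cluster" %in% names(df)) p <- p + ggplot2::facet_wrap(~cluster)
  p
}

#' Phase-fraction stacked bars
#'
#' @param fractions Tibble from [phase_fractions()].
#' @return A ggplot object.
#' @export
plot_phase_fractions <- function(fractions) {
  keys <- setdiff(names(fractions), c("phase", "n", "fraction"))
  df <- fractions
  df$stratum <- do.call(paste, c(df[keys], sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$fraction,
                                   fill = .data$phase)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' GSEA enrichment summary plot
#'
#' @param object A [gsea_preranked()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tidy(object)
  df$set <- stats::reorder(df$set, df$nes)
  ggplot2::ggplot(df, ggplot2::aes(.data$nes, .data$set,
                                   fill = .data$fdr < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NES", y = NULL, fill = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
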