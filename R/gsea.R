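# Pre-ranked gene-set enrichment and Fisher over-representation.
#
# The enrichment score is the signed extremum of a running sum over the
# ranked gene list: hits increment proportionally to |statistic|^weight
# (normalized to sum 1 within the set), misses decrement by 1/(N - n_set).
# The null is built by permuting gene labels (sampling random sets of the
# same size), NES = ES divided by the mean |null ES| of matching sign, and
# the empirical p is two-sided within the matching-sign null.

# ES via the piecewise-linear shortcut: extrema can only occur immediately
# before or at a hit position.
.gsea_es <- function(stat_sorted, hit_pos, weight = 1) {
  N <- length(stat_sorted)
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(stat_sorted[hit_pos])^weight
  if (sum(w) == 0) w <- rep(1, m)  # degenerate: all-zero stats
  w <- w / sum(w)
  miss <- 1 / (N - m)
  cum_hit <- cumsum(w)
  at_hit <- cum_hit - (hit_pos - seq_len(m)) * miss
  before_hit <- c(0, cum_hit[-m]) - (hit_pos - seq_len(m)) * miss
  cand <- c(at_hit, before_hit)
  es <- unname(cand[which.max(abs(cand))])
  # leading edge: genes up to (positive ES) / after (negative ES) the extremum
  if (es >= 0) {
    peak <- hit_pos[which.max(at_hit)]
    le <- hit_pos[hit_pos <= peak]
  } else {
    trough <- hit_pos[which.min(before_hit)]
    le <- hit_pos[hit_pos >= trough]
  }
  list(es = es, leading_edge = le)
}

#' Pre-ranked gene-set enrichment
#'
#' @param stats Named numeric vector of per-gene ranking statistics (e.g.
#'   log2 fold changes); no missing values.
#' @param sets Named list of gene sets, or a single character vector.
#' @param weight Hit-weight exponent on |statistic| (default 1).
#' @param n_perm Gene-label permutations for the null (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A tibble of class `gsea_result`, one row per testable set:
#'   `set`, `size` (genes in set and universe), `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (list column of gene names). Sets overlapping the
#'   universe in fewer than 2 genes are skipped with a warning. FDR is
#'   Benjamini-Hochberg within each ES sign stratum.
#' @export
gsea_preranked <- function(stats, sets, weight = 1, n_perm = 1000, seed = 1L) {
  if (anyNA(stats)) abort("Ranking statistics must not contain NA.")
  if (!is.list(sets)) sets <- list(set = sets)
  ord <- order(stats, decreasing = TRUE)
  stat_sorted <- stats[ord]
  genes_sorted <- names(stat_sorted)
  N <- length(stats)

  rows <- list()
  with_seed(seed, {
    for (nm in names(sets)) {
      hit_pos <- which(genes_sorted %in% sets[[nm]])
      m <- length(hit_pos)
      if (m < 2 || m >= N) {
        warn(sprintf("Skipping set '%s': overlap with universe is %d.", nm, m))
        next
      }
      obs <- .gsea_es(stat_sorted, hit_pos, weight)
      null_es <- vapply(seq_len(n_perm), function(i) {
        .gsea_es(stat_sorted, sample.int(N, m), weight)$es
      }, numeric(1))
      same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      if (length(same_sign)) {
        nes <- obs$es / mean(abs(same_sign))
        p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
      } else {
        nes <- NA_real_
        p <- 1 / (1 + n_perm)
      }
      rows[[nm]] <- tibble(
        set = nm, size = m, es = obs$es, nes = nes, p = p,
        leading_edge = list(genes_sorted[obs$leading_edge])
      )
    }
  })
  res <- list_rbind(rows)
  if (is.null(res) || !nrow(res)) {
    res <- tibble(set = character(), size = integer(), es = numeric(),
                  nes = numeric(), p = numeric(), fdr = numeric(),
                  leading_edge = list())
    class(res) <- c("gsea_result", class(res))
    return(res)
  }
  res$fdr <- NA_real_
  pos <- res$es >= 0
  if (any(pos)) res$fdr[pos] <- p.adjust(res$p[pos], method = "BH")
  if (any(!pos)) res$fdr[!pos] <- p.adjust(res$p[!pos], method = "BH")
  res <- res[, c("set", "size", "es", "nes", "p", "fdr", "leading_edge")]
  class(res) <- c("gsea_result", class(res))
  res
}

#' @export
tidy.gsea_result <- function(x, ...) {
  out <- x
  out$leading_edge <- vapply(out$leading_edge, paste, character(1), collapse = ",")
  class(out) <- setdiff(class(out), "gsea_result")
  out
}

#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$fdr < 0.05, na.rm = TRUE))
}

#' Fisher over-representation analysis
#'
#' One-sided hypergeometric tail on the overlap of a query gene list with
#' each set, against a fixed universe, with the sample odds ratio of the
#' 2x2 table and Benjamini-Hochberg correction across sets.
#'
#' @param query Character vector of query genes (e.g. retained DEGs); must
#'   be a subset of `universe` and non-empty.
#' @param sets Named list of gene sets (intersected with the universe).
#' @param universe Character vector of all genes considered.
#' @return A tibble with `set`, `overlap`, `size_set`, `size_query`,
#'   `odds_ratio`, `p`, `p_adj`.
#' @export
ora_fisher <- function(query, sets, universe) {
  if (!length(query)) abort("Empty query gene list.")
  if (!all(query %in% universe)) abort("Query genes must be a subset of the universe.")
  query <- unique(query)
  N <- length(unique(universe))
  nq <- length(query)
  rows <- imap(sets, function(g, nm) {
    g <- intersect(g, universe)
    k <- length(intersect(query, g))
    ns <- length(g)
    p <- phyper(k - 1, ns, N - ns, nq, lower.tail = FALSE)
    a <- k; b <- nq - k; c_ <- ns - k; d <- N - nq - ns + k
    or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    tibble(set = nm, overlap = k, size_set = ns, size_query = nq,
           odds_ratio = or, p = p)
  })
  res <- list_rbind(rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}
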