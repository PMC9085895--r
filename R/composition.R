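# Cluster-composition analysis: the Ro/e statistic with chi-square tests.
#
# Ro/e is the ratio of the observed to the expected number of cells of a
# group in a cluster, with expectation taken from the pooled margins of the
# clusters x groups contingency table. Ro/e > 1 is read as an increased
# cluster in that group, Ro/e < 1 as decreased.

# Closed-form 2x2 chi-square without continuity correction.
.chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(list(stat = NA_real_, p = NA_real_))
  stat <- n * (a * d - b * c)^2 / denom
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Ro/e cluster-composition table
#'
#' Builds the clusters x groups contingency table, computes expected counts
#' from the margins, the per-cell Ro/e ratio, and a per-(cluster, group)
#' chi-square test on the 2x2 collapse (in/out of cluster x in/out of group,
#' 1 df, no continuity correction). An omnibus clusters x groups chi-square
#' is attached as an attribute and reported by [glance()].
#'
#' @param data A data frame with one row per cell.
#' @param cluster,group Column names (strings) holding the cluster and group
#'   labels (defaults `"cluster"`, `"group"`).
#' @return A tibble of class `roe_result` with columns `cluster`, `group`,
#'   `observed`, `expected`, `roe`, `chisq`, `p` and `shift`
#'   (`increased`/`decreased`/`unchanged`).
#' @export
#' @examples
#' cells <- data.frame(
#'   cluster = rep(c("X", "Y"), c(100, 100)),
#'   group = c(rep("NC", 60), rep("UT", 40), rep("NC", 40), rep("UT", 60))
#' )
#' roe_table(cells)
roe_table <- function(data, cluster = "cluster", group = "group") {
  cl <- as.character(data[[cluster]])
  gr <- as.character(data[[group]])
  if (anyNA(cl) || anyNA(gr)) abort("Every cell needs a cluster and a group label.")
  tab <- table(cl, gr)
  empty_cl <- rownames(tab)[rowSums(tab) == 0]
  empty_gr <- colnames(tab)[colSums(tab) == 0]
  if (length(empty_cl) || length(empty_gr)) {
    warn("Dropping empty cluster/group margins.")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  n <- sum(tab)
  row_tot <- rowSums(tab)
  col_tot <- colSums(tab)
  out <- list()
  for (ci in rownames(tab)) {
    for (gi in colnames(tab)) {
      obs <- tab[ci, gi]
      expd <- row_tot[[ci]] * col_tot[[gi]] / n
      roe <- if (expd > 0) obs / expd else NA_real_
      a <- obs
      b <- row_tot[[ci]] - obs
      c_ <- col_tot[[gi]] - obs
      d <- n - row_tot[[ci]] - col_tot[[gi]] + obs
      ch <- .chisq_2x2(a, b, c_, d)
      shift <- if (is.na(roe)) {
        NA_character_
      } else if (isTRUE(all.equal(roe, 1, tolerance = 1e-12))) {
        "unchanged"
      } else if (roe > 1) "increased" else "decreased"
      out[[paste(ci, gi)]] <- tibble(
        cluster = ci, group = gi, observed = as.numeric(obs),
        expected = expd, roe = roe, chisq = ch$stat, p = ch$p, shift = shift
      )
    }
  }
  res <- list_rbind(out)
  omni <- suppressWarnings(chisq.test(tab, correct = FALSE))
  attr(res, "omnibus") <- list(statistic = unname(omni$statistic),
                               df = unname(omni$parameter),
                               p = omni$p.value)
  attr(res, "n_cells") <- n
  class(res) <- c("roe_result", class(res))
  res
}

#' Per-donor Ro/e replicates
#'
#' Recomputes Ro/e within each donor, against the pooled cluster proportions
#' of the full table: a donor's expected count in a cluster is the donor's
#' cell total times the pooled fraction of cells in that cluster. Donors
#' with zero cells are skipped.
#'
#' @inheritParams roe_table
#' @param donor Column name of donor identifiers (default `"donor"`).
#' @return A list with `by_donor` (tibble: cluster, group, donor, observed,
#'   expected, roe) and `summary` (tibble: cluster, group, mean_roe, sem,
#'   n_donors).
#' @export
roe_per_donor <- function(data, cluster = "cluster", group = "group",
                          donor = "donor") {
  cl <- as.character(data[[cluster]])
  gr <- as.character(data[[group]])
  dn <- as.character(data[[donor]])
  pool_frac <- prop.table(table(cl))
  rows <- list()
  for (d in unique(dn)) {
    idx <- dn == d
    if (!sum(idx)) next
    g <- unique(gr[idx])
    n_d <- sum(idx)
    obs <- table(factor(cl[idx], levels = names(pool_frac)))
    for (ci in names(pool_frac)) {
      expd <- n_d * pool_frac[[ci]]
      rows[[paste(d, ci)]] <- tibble(
        cluster = ci, group = g[1], donor = d,
        observed = as.numeric(obs[[ci]]), expected = expd,
        roe = if (expd > 0) obs[[ci]] / expd else NA_real_
      )
    }
  }
  by_donor <- list_rbind(rows)
  summary <- by_donor |>
    group_by(.data$cluster, .data$group) |>
    summarise(
      mean_roe = mean(.data$roe),
      sem = if (dplyr::n() > 1) sd(.data$roe) / sqrt(dplyr::n()) else 0,
      n_donors = dplyr::n(),
      .groups = "drop"
    )
  list(by_donor = by_donor, summary = summary)
}

#' @export
tidy.roe_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "roe_result")
  attr(out, "omnibus") <- NULL
  attr(out, "n_cells") <- NULL
  out
}

#' @export
glance.roe_result <- function(x, ...) {
  om <- attr(x, "omnibus")
  tibble(
    n_cells = attr(x, "n_cells"),
    n_clusters = length(unique(x$cluster)),
    n_groups = length(unique(x$group)),
    omnibus_chisq = om$statistic,
    omnibus_df = om$df,
    omnibus_p = om$p
  )
}

#' @export
print.roe_result <- function(x, ...) {
  om <- attr(x, "omnibus")
  cat(sprintf("Ro/e composition table (%d cells; omnibus chi-square %.3g, df %d, p %.3g)\n",
              attr(x, "n_cells"), om$statistic, om$df, om$p))
  NextMethod()
}
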