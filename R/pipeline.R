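# End-to-end orchestration: simulate -> qc -> cluster -> composition ->
# scores -> differential expression / enrichment, with every stage's seed
# derived deterministically from one global seed and all outputs written as
# TSV plus a machine-readable JSON summary.

#' Pipeline configuration
#'
#' @param synth Named list of [synth_config()] overrides.
#' @param qc A [qc_params()] object.
#' @param target_n_hvgs HVGs for clustering (default 1168, the integrated-run
#'   value; use 422 for a single-group run).
#' @param n_components,knn_k,resolution Clustering parameters (defaults 20,
#'   20, 1.0).
#' @param comparisons List of group pairs to compare (default NC:UT, UT:GCR,
#'   GCR:GCNR).
#' @param score_sets Names of gene sets to score (default: the planted
#'   functional programs).
#' @param n_perm GSEA permutations (default 200 for pipeline runs).
#' @param seed Global seed; every stochastic stage derives its own seed from
#'   it.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(synth = list(), qc = qc_params(),
                            target_n_hvgs = 1168, n_components = 20,
                            knn_k = 20, resolution = 1.0,
                            comparisons = list(c("NC", "UT"), c("UT", "GCR"),
                                               c("GCR", "GCNR")),
                            score_sets = c("apoptosis", "p53_signaling",
                                           "g1s_transition", "dna_replication",
                                           "type1_ifn", "proliferation",
                                           "ribosomal_proteins"),
                            n_perm = 200, seed = 1L) {
  structure(list(
    synth = synth, qc = qc, target_n_hvgs = target_n_hvgs,
    n_components = n_components, knn_k = knn_k, resolution = resolution,
    comparisons = comparisons, score_sets = score_sets, n_perm = n_perm,
    seed = seed
  ), class = "run_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$qc <- unclass(x$qc)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  qc <- do.call(qc_params, x$qc)
  x$qc <- NULL
  x$comparisons <- lapply(x$comparisons, unlist)
  do.call(pipeline_config, c(x, list(qc = qc)))
}

.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]])) {
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Majority-truth mapping from recovered clusters to planted subpopulations.
map_clusters_to_truth <- function(clusters, truth) {
  joined <- left_join(clusters, truth, by = "cell")
  joined <- joined[!is.na(joined$subpop), ]
  tab <- table(joined$cluster, joined$subpop)
  mapping <- colnames(tab)[apply(tab, 1, which.max)]
  setNames(mapping, rownames(tab))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulation, QC, clustering, the batch-control check, Ro/e
#' composition (pooled and per donor), gene-set and cell-cycle scoring with
#' Wilcoxon-Holm comparisons, per-comparison differential expression with
#' the retention filter, pre-ranked GSEA and Fisher over-representation,
#' writing each stage's table under `out_dir` together with `summary.json`
#' and a run log. When the cohort carries a truth channel, recovered
#' clusters are relabeled by their majority planted subpopulation so the
#' composition and score tables read in planted terms.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with every stage result plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("erythrocomp %s", as.character(utils::packageVersion("erythrocomp"))),
                 sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("global seed %d", config$seed))
  stage <- function(msg) log_lines <<- c(log_lines, msg)

  # -- simulate
  synth_cfg <- do.call(synth_config, c(config$synth,
                                       list(seed = stage_seed(config$seed, "simulate"))))
  cohort <- simulate_cohort(synth_cfg)
  stage(sprintf("simulate: %d cells x %d genes (seed %d)",
                nrow(cohort$counts), ncol(cohort$counts), synth_cfg$seed))

  # -- qc
  qc <- apply_qc(cohort$counts, config$qc)
  stage(sprintf("qc: kept %d of %d cells, %d genes",
                nrow(qc$counts), nrow(cohort$counts), ncol(qc$counts)))
  .write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  ann <- cohort$annotations[match(rownames(qc$counts), cohort$annotations$cell), ]
  truth <- cohort$truth[match(rownames(qc$counts), cohort$truth$cell), ]

  layer <- log2_layer(qc$counts, config$qc$pseudocount)
  norm <- normalized_layer(qc$counts)

  # -- cluster
  hvgs <- select_hvgs(layer, target_n = config$target_n_hvgs)
  emb <- reduce_dims(layer, hvgs, config$n_components)
  clusters <- cluster_graph(emb, k = config$knn_k,
                            resolution = config$resolution,
                            seed = stage_seed(config$seed, "cluster"))
  stage(sprintf("cluster: %d HVGs, %d dims, resolution %.2f -> %d clusters",
                length(hvgs), ncol(emb), config$resolution,
                nlevels(clusters$cluster)))
  mixing <- tryCatch(
    batch_control_check(emb, ann$is_control, ann$plate),
    error = function(e) NULL
  )
  if (!is.null(mixing)) {
    stage(sprintf("batch control: mixing score %.3f (%s)", mixing$score,
                  if (mixing$pass) "pass" else "FAIL"))
  }
  mapping <- map_clusters_to_truth(clusters, truth)
  clusters$subpop <- unname(mapping[as.character(clusters$cluster)])
  .write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  .write_tsv(cbind(cell = rownames(emb), as.data.frame(emb)),
             file.path(out_dir, "embedding.tsv"))

  cells <- left_join(clusters, ann, by = "cell")
  cells$label <- cells$subpop  # planted-subpop naming of recovered clusters

  # -- composition
  roe <- roe_table(cells, cluster = "label", group = "group")
  roe_donor <- roe_per_donor(cells, cluster = "label", group = "group")
  .write_tsv(tidy(roe), file.path(out_dir, "roe.tsv"))
  .write_tsv(roe_donor$by_donor, file.path(out_dir, "roe_by_donor.tsv"))
  stage(sprintf("composition: omnibus chi-square p = %.3g",
                attr(roe, "omnibus")$p))

  # -- gene-set scores
  sets <- cohort$gene_sets[intersect(config$score_sets, names(cohort$gene_sets))]
  scores <- score_genesets(layer, sets) |>
    left_join(cells[, c("cell", "group", "label")], by = "cell") |>
    rename(cluster = "label")
  comparisons <- compare_scores(scores, config$comparisons)
  .write_tsv(scores, file.path(out_dir, "scores.tsv"))
  .write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"))

  # -- cell cycle
  phases <- cellcycle_scores(layer, cohort$gene_sets$s_phase,
                             cohort$gene_sets$g2m_phase,
                             seed = stage_seed(config$seed, "cellcycle"))
  phases <- left_join(phases, cells[, c("cell", "group", "label")], by = "cell")
  frac <- phase_fractions(phases, cluster = "label", group = "group")
  .write_tsv(phases, file.path(out_dir, "phases.tsv"))
  .write_tsv(frac, file.path(out_dir, "phase_fractions.tsv"))

  # -- markers and per-comparison DE / enrichment
  markers <- find_markers(norm, clusters)
  .write_tsv(markers$top, file.path(out_dir, "markers.tsv"))
  de_list <- list()
  gsea_list <- list()
  ora_list <- list()
  for (cmp in config$comparisons) {
    nm <- paste0(cmp[1], "_vs_", cmp[2])
    a <- cells$cell[cells$group == cmp[1]]
    b <- cells$cell[cells$group == cmp[2]]
    if (length(a) < 3 || length(b) < 3) next
    de <- de_between(norm, a, b)
    de_list[[nm]] <- de
    .write_tsv(de, file.path(out_dir, paste0("de_", nm, ".tsv")))
    ranked <- setNames(de$log2_fc, de$gene)
    gsea <- suppressWarnings(
      gsea_preranked(ranked, cohort$gene_sets, n_perm = config$n_perm,
                     seed = stage_seed(config$seed, paste0("gsea_", nm)))
    )
    gsea_list[[nm]] <- gsea
    .write_tsv(tidy(gsea), file.path(out_dir, paste0("gsea_", nm, ".tsv")))
    degs <- filter_degs(de)
    if (nrow(degs)) {
      ora <- ora_fisher(degs$gene, cohort$gene_sets, de$gene)
      ora_list[[nm]] <- ora
      .write_tsv(ora, file.path(out_dir, paste0("ora_", nm, ".tsv")))
    }
    stage(sprintf("de %s: %d genes tested, %d retained", nm,
                  attr(de, "n_tested"), nrow(degs)))
  }

  summary <- list(
    seed = config$seed,
    n_cells_simulated = nrow(cohort$counts),
    n_cells_qc = nrow(qc$counts),
    n_genes_qc = ncol(qc$counts),
    n_clusters = nlevels(clusters$cluster),
    cluster_sizes = as.list(table(clusters$cluster)),
    cluster_to_subpop = as.list(mapping),
    batch_mixing = if (is.null(mixing)) NULL else mixing[c("score", "pass")],
    roe = tidy(roe),
    score_comparisons = comparisons,
    deg_counts = lapply(de_list, function(d) nrow(filter_degs(d))),
    gsea = lapply(gsea_list, function(g) tidy(g)[, c("set", "es", "nes", "p", "fdr")])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(
    cohort = cohort, qc = qc, clusters = clusters, embedding = emb,
    mixing = mixing, roe = roe, roe_donor = roe_donor, scores = scores,
    comparisons = comparisons, phases = phases, phase_fractions = frac,
    markers = markers, de = de_list, gsea = gsea_list, ora = ora_list,
    summary = summary
  ))
}

#' Render a human-readable report for a completed run
#'
#' Reads the stage tables written by [run_pipeline()] and assembles a single
#' markdown report; missing stages are marked unavailable. Regeneration is
#' idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output markdown path (default `report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
report_run <- function(run_dir, path = file.path(run_dir, "report.md")) {
  section <- function(title, file, render) {
    f <- file.path(run_dir, file)
    body <- if (file.exists(f)) {
      render(read.table(f, sep = "\t", header = TRUE))
    } else {
      "*unavailable*"
    }
    c(paste0("## ", title), "", body, "")
  }
  md_table <- function(df, n = 15) {
    df <- head(df, n)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  lines <- c("# erythrocomp run report", "")
  lines <- c(lines, section("QC", "qc_report.tsv", function(df) {
    sprintf("%d of %d cells kept (%d too few genes, %d too many).",
            sum(df$kept), nrow(df),
            sum(df$reason == "too_few_genes", na.rm = TRUE),
            sum(df$reason == "too_many_genes", na.rm = TRUE))
  }))
  lines <- c(lines, section("Clusters", "clusters.tsv", function(df) {
    md_table(as.data.frame(table(cluster = df$cluster)))
  }))
  lines <- c(lines, section("Composition (Ro/e)", "roe.tsv", md_table))
  lines <- c(lines, section("Score comparisons", "comparisons.tsv", md_table))
  lines <- c(lines, section("Phase fractions", "phase_fractions.tsv", md_table))
  lines <- c(lines, section("Cluster markers", "markers.tsv", md_table))
  gsea_files <- list.files(run_dir, pattern = "^gsea_.*\\.tsv$")
  if (length(gsea_files)) {
    for (f in gsea_files) {
      lines <- c(lines, section(paste("GSEA", sub("^gsea_(.*)\\.tsv$", "\\1", f)),
                                f, function(df) md_table(df[order(df$p), setdiff(names(df), "leading_edge")])))
    }
  } else {
    lines <- c(lines, "## GSEA", "", "*unavailable*", "")
  }
  writeLines(lines, path)
  invisible(path)
}
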