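make_layer <- function(m) {
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

test_that("differential expression handles null genes and Bonferroni", {
  set.seed(20)
  counts <- make_layer(matrix(rpois(40 * 3, 10), 40, 3))
  counts[, 2] <- counts[, 1]  # two genes, identical distribution construction
  nl <- normalized_layer(counts)
  de <- de_between(nl, paste0("c", 1:20), paste0("c", 21:40), min_pct = 0)
  expect_equal(attr(de, "n_tested"), 3)
  expect_equal(de$p_adj, pmin(1, de$p_raw * 3))
  null_gene <- de[de$gene == "g1", ]
  expect_gt(null_gene$p_raw, 0.05)
  expect_lt(abs(null_gene$avg_fc - 1), 0.25)
  expect_error(de_between(nl, paste0("c", 1:2), paste0("c", 3:40)), "at least 3")
})

test_that("differential expression is antisymmetric in the sides", {
  set.seed(21)
  counts <- make_layer(matrix(rpois(60 * 30, 8), 60, 30))
  counts[1:30, 1:5] <- counts[1:30, 1:5] + rpois(30 * 5, 10)
  nl <- normalized_layer(counts)
  a <- paste0("c", 1:30); b <- paste0("c", 31:60)
  ab <- de_between(nl, a, b)
  ba <- de_between(nl, b, a)
  common <- intersect(ab$gene, ba$gene)
  i <- match(common, ab$gene); j <- match(common, ba$gene)
  expect_equal(ab$avg_fc[i], 1 / ba$avg_fc[j], tolerance = 1e-10)
  expect_equal(ab$p_raw[i], ba$p_raw[j], tolerance = 1e-10)
})

test_that("the DEG retention rule applies both thresholds literally", {
  de <- tibble::tibble(
    gene = paste0("g", 1:4),
    avg_fc = c(1.25, 1.30, 2.0, 0.5),
    log2_fc = log2(avg_fc),
    statistic = 0, p_raw = 0,
    p_adj = c(0.04, 0.04, 0.05, 0.01),
    pct_a = 1, pct_b = 1,
    direction = c("up", "up", "up", "down")
  )
  class(de) <- c("de_table", class(de))
  kept <- filter_degs(de)
  # p 0.04 / fc 1.25 fails the fold-change bound; p 0.05 fails the strict p;
  # fc 1.30 at p 0.04 is retained, as is the down-regulated 0.5
  expect_identical(kept$gene, c("g2", "g4"))
})

test_that("a planted two-fold gene is recovered with high power", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    counts <- make_layer(matrix(rpois(200 * 150, 6), 200, 150))
    counts[1:100, 1] <- rpois(100, 12)  # 2-fold planted gene
    nl <- normalized_layer(counts)
    de <- de_between(nl, paste0("c", 1:100), paste0("c", 101:200))
    kept <- filter_degs(de)
    if ("g1" %in% kept$gene) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("one-vs-rest markers find a single discriminating gene", {
  set.seed(22)
  counts <- make_layer(matrix(rpois(40 * 20, 10), 40, 20))
  counts[1:20, 7] <- counts[1:20, 7] + 60
  nl <- normalized_layer(counts)
  clusters <- tibble::tibble(cell = paste0("c", 1:40),
                             cluster = rep(c("A", "B"), each = 20))
  mk <- find_markers(nl, clusters, top_n = 10)
  strong_a <- filter_degs(mk$tables$A)
  expect_identical(strong_a$gene, "g7")
  expect_true(all(table(mk$top$cluster) <= 10))
})

test_that("GSEA enrichment scores match the brute-force running sum", {
  # the 5-gene worked example
  stats <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  res <- gsea_preranked(stats, list(s = c("g1", "g3")), n_perm = 50, seed = 1)
  expect_equal(res$es, oracle_gsea_es(sort(stats, decreasing = TRUE), c(1, 3)),
               tolerance = 1e-12)
  # random instances, N <= 50
  set.seed(23)
  for (rep in 1:25) {
    N <- sample(10:50, 1)
    stats <- setNames(rnorm(N), paste0("g", seq_len(N)))
    m <- sample(2:(N - 2), 1)
    set_genes <- sample(names(stats), m)
    res <- suppressWarnings(
      gsea_preranked(stats, list(s = set_genes), n_perm = 10, seed = rep)
    )
    ord <- sort(stats, decreasing = TRUE)
    hits <- which(names(ord) %in% set_genes)
    expect_equal(res$es, oracle_gsea_es(ord, hits), tolerance = 1e-12)
    expect_lte(abs(res$es), 1)
    expect_true(all(res$leading_edge[[1]] %in% set_genes))
  }
})

test_that("a set of the top-ranked genes approaches the maximal score", {
  N <- 1000
  stats <- setNames(sort(rexp(N), decreasing = TRUE), paste0("g", 1:N))
  res <- gsea_preranked(stats, list(top = paste0("g", 1:5)), n_perm = 20,
                        seed = 2)
  expect_gt(res$es, 0.95)
  expect_identical(sort(res$leading_edge[[1]]), sort(paste0("g", 1:5)))
})

test_that("GSEA agrees with an independent implementation on the ES", {
  set.seed(24)
  stats <- setNames(rnorm(200), paste0("g", 1:200))
  set_genes <- sample(names(stats), 25)
  ours <- gsea_preranked(stats, list(s = set_genes), n_perm = 10, seed = 3)
  ref <- fgsea::calcGseaStat(sort(stats, decreasing = TRUE),
                             selectedStats = which(names(sort(stats, decreasing = TRUE))
                                                   %in% set_genes),
                             gseaParam = 1)
  expect_equal(ours$es, ref, tolerance = 1e-10)
})

test_that("NES on random sets centers near unit magnitude", {
  set.seed(25)
  stats <- setNames(rnorm(300), paste0("g", 1:300))
  nes <- replicate(10, {
    gsea_preranked(stats, list(s = sample(names(stats), 20)),
                   n_perm = 200, seed = sample.int(1e6, 1))$nes
  })
  expect_lt(abs(mean(abs(nes)) - 1), 0.25)
})

test_that("over-representation p matches the hypergeometric tail sum", {
  universe <- paste0("g", 1:100)
  gene_set <- paste0("g", 1:10)
  query <- c(paste0("g", 1:5), paste0("g", 50:54))  # overlap 5
  res <- ora_fisher(query, list(s = gene_set), universe)
  oracle <- sum(vapply(5:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-10)
  expect_equal(res$p, 6.9e-5, tolerance = 0.02)
  expect_equal(res$overlap, 5)
  # disjoint set: p = 1 under the upper-tail convention
  res0 <- ora_fisher(paste0("g", 60:69), list(s = gene_set), universe)
  expect_equal(res0$p, 1)
  # query = set achieves the minimal p for those margins
  res_min <- ora_fisher(gene_set, list(s = gene_set), universe)
  expect_equal(res_min$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_error(ora_fisher(character(0), list(s = gene_set), universe), "Empty")
  expect_error(ora_fisher("not_in_universe", list(s = gene_set), universe),
               "subset")
})

test_that("ORA agrees in direction with Fisher's exact test", {
  universe <- paste0("g", 1:200)
  res <- ora_fisher(paste0("g", 1:20), list(s = paste0("g", 1:15)), universe)
  ref <- fisher.test(matrix(c(15, 5, 0, 180), 2, byrow = TRUE),
                     alternative = "greater")
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})
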