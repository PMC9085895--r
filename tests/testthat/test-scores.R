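toy_layer <- function() {
  counts <- rbind(cell1 = c(A = 3, B = 1, C = 7),
                  cell2 = c(A = 0, B = 0, C = 0))
  log2_layer(counts, 1)
}

test_that("the gene-set score sums log2 UMIs over the set", {
  l <- toy_layer()
  expect_equal(geneset_score(l, c("A", "B"))$score, c(3, 0))
  expect_equal(geneset_score(l, "C")$score, c(3, 0))
  expect_equal(geneset_score(l, character(0))$score, c(0, 0))
  expect_warning(out <- geneset_score(l, c("nope1", "nope2"), "missing"),
                 "no genes")
  expect_equal(out$score, c(0, 0))
  expect_equal(attr(geneset_score(l, c("A", "B", "zzz")), "frac_genes_present"),
               2 / 3)
})

test_that("scores are additive over disjoint sets", {
  set.seed(9)
  counts <- matrix(rpois(50 * 30, 4), 50, 30,
                   dimnames = list(paste0("c", 1:50), paste0("g", 1:30)))
  l <- log2_layer(counts)
  a <- geneset_score(l, paste0("g", 1:10))$score
  b <- geneset_score(l, paste0("g", 11:25))$score
  ab <- geneset_score(l, paste0("g", 1:25))$score
  expect_equal(ab, a + b, tolerance = 1e-12)
})

test_that("the proliferation score follows the same summation contract", {
  counts <- rbind(cellA = c(PCNA = 15))
  l <- log2_layer(counts, 1)
  expect_equal(proliferation_score(l, "PCNA")$score, 4)
  expect_equal(proliferation_score(l, "PCNA")$set, "proliferation")
})

test_that("exact Wilcoxon branch matches enumeration, ties fall back", {
  sc <- tibble::tibble(
    cell = paste0("c", 1:6), set = "s", score = c(1, 2, 3, 4, 5, 6),
    group = rep(c("a", "b"), each = 3)
  )
  res <- compare_scores(sc, list(c("a", "b")))
  expect_equal(res$p, 0.1)  # 2/20 enumerated assignments are as extreme
  expect_true(res$exact)
  expect_equal(res$p, oracle_wilcox_p(1:3, 4:6))
  # identical groups: fully tied, p = 1
  sc$score <- rep(5, 6)
  res2 <- compare_scores(sc, list(c("a", "b")))
  expect_equal(res2$p, 1)
  expect_false(res2$exact)
})

test_that("exact p equals the enumeration oracle across small sample sizes", {
  set.seed(10)
  for (n in c(2, 4, 7)) {
    for (m in c(3, 6, 8)) {
      x <- sample(seq_len(100), n)
      y <- sample(setdiff(seq_len(100), x), m)
      got <- suppressWarnings(
        wilcox.test(x, y, exact = TRUE, correct = FALSE)
      )$p.value
      sc <- tibble::tibble(cell = paste0("c", seq_len(n + m)), set = "s",
                           score = c(x, y),
                           group = rep(c("a", "b"), c(n, m)))
      res <- compare_scores(sc, list(c("a", "b")))
      expect_equal(res$p, oracle_wilcox_p(x, y), tolerance = 1e-12)
      expect_equal(res$p, got, tolerance = 1e-12)
    }
  }
})

test_that("Holm correction within a panel family matches the step-down rule", {
  set.seed(11)
  sc <- tibble::tibble(
    cell = paste0("c", 1:120), set = "s",
    score = rnorm(120) + rep(c(0, 0.7, 0.2, 1), each = 30),
    group = rep(c("NC", "UT", "GCR", "GCNR"), each = 30)
  )
  res <- compare_scores(sc, list(c("NC", "UT"), c("UT", "GCR"),
                                 c("GCR", "GCNR")))
  expect_equal(res$p_holm, oracle_holm(res$p), tolerance = 1e-12)
  expect_true(all(res$p_holm >= res$p))
  # monotone: ordering by raw p is preserved in adjusted p
  expect_true(all(diff(res$p_holm[order(res$p)]) >= -1e-12))
})

test_that("cell-cycle scores separate planted phase programs", {
  set.seed(12)
  n_genes <- 300
  genes <- sprintf("g%03d", 1:n_genes)
  s_set <- genes[1:20]
  g2m_set <- genes[21:40]
  # continuous background abundance spectrum so every expression bin holds
  # comparable control genes
  rates <- exp(seq(log(5), log(160), length.out = n_genes))[sample(n_genes)]
  base <- matrix(rpois(90 * n_genes, rep(rates, each = 90)), 90, n_genes,
                 dimnames = list(paste0("c", 1:90), genes))
  base[, c(s_set, g2m_set)] <- rpois(90 * 40, 20)  # phase genes: rate 20 at rest
  base[1:30, s_set] <- rpois(30 * 20, 80)    # S cells
  base[31:60, g2m_set] <- rpois(30 * 20, 80) # G2M cells
  l <- log2_layer(base)
  ph <- cellcycle_scores(l, s_set, g2m_set, seed = 3)
  expect_true(all(ph$s_score[1:30] > 0))
  expect_true(all(ph$g2m_score[1:30] < ph$s_score[1:30]))
  expect_equal(ph$phase[1:30], rep("S", 30))
  expect_equal(ph$phase[31:60], rep("G2M", 30))
  expect_true(mean(ph$phase[61:90] == "G1") > 0.9)
  # uniform matrix: both scores about zero
  flat <- log2_layer(matrix(10, 40, n_genes,
                            dimnames = list(paste0("c", 1:40), genes)))
  ph0 <- cellcycle_scores(flat, s_set, g2m_set, seed = 3)
  expect_true(all(abs(ph0$s_score) < 1e-9))
  expect_true(all(abs(ph0$g2m_score) < 1e-9))
})

test_that("cell-cycle scoring is invariant to a constant expression offset", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:200)
  l <- matrix(rnorm(60 * 200, 3), 60, 200,
              dimnames = list(paste0("c", 1:60), genes))
  a <- cellcycle_scores(l, genes[1:15], genes[16:30], seed = 5)
  b <- cellcycle_scores(l + 2.5, genes[1:15], genes[16:30], seed = 5)
  expect_equal(a$s_score, b$s_score, tolerance = 1e-12)
  expect_equal(a$g2m_score, b$g2m_score, tolerance = 1e-12)
})

test_that("phase assignment follows the decision rule", {
  sc <- tibble::tibble(s_score = c(0.5, -0.2, 0.3, -0.1, 0.2),
                       g2m_score = c(-0.1, -0.3, 0.4, 0.2, 0.2))
  expect_equal(assign_phase(sc), c("S", "G1", "G2M", "G2M", "G2M"))
})

test_that("phase fractions sum to one within every stratum", {
  set.seed(14)
  df <- data.frame(
    phase = sample(c("G1", "S", "G2M"), 200, replace = TRUE),
    cluster = sample(c("C0", "C3"), 200, replace = TRUE),
    group = sample(c("NC", "UT"), 200, replace = TRUE)
  )
  fr <- phase_fractions(df)
  sums <- tapply(fr$fraction, paste(fr$cluster, fr$group), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
})
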