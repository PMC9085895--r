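test_that("default configuration reproduces the cohort layout", {
  cfg <- synth_config()
  expect_equal(sum(cfg$group_sizes), 1392)
  expect_equal(unname(cfg$group_sizes[c("NC", "UT", "GCR", "GCNR")]),
               c(426, 428, 276, 262))
  expect_equal(cfg$plate_size, 96L)
  expect_equal(cfg$controls_per_plate, 16L)
  expect_true(all(abs(rowSums(cfg$subpop_proportions) - 1) < 1e-9))
})

test_that("configuration overrides merge and invalid ones error", {
  cfg <- synth_config(group_sizes = c(NC = 10))
  expect_equal(unname(cfg$group_sizes["NC"]), 10)
  expect_equal(unname(cfg$group_sizes["UT"]), 428)
  expect_error(synth_config(subpop_proportions = list(NC = c(0.5, 0.5, 0, 0, 0.2))),
               "sum to 1")
  expect_error(synth_config(not_a_field = 1), "Unknown")
  expect_error(synth_config(nb_dispersion = -1), "positive")
  expect_error(synth_config(n_genes = 100, mean_detected_target = 50),
               "smaller than the union")
})

test_that("simulation is byte-for-byte reproducible from its seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotations, b$annotations)
  c2 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(a$counts, c2$counts))
})

test_that("every plate carries the configured batch-control cells", {
  co <- full_cohort()
  ctrl <- co$annotations[co$annotations$is_control, ]
  expect_true(all(table(ctrl$plate) == 16))
  expect_equal(length(unique(ctrl$plate)),
               length(unique(co$annotations$plate)))
  expect_equal(unique(ctrl$donor), "NC_d1")
  expect_equal(unique(ctrl$group), "NC")
  # controls are counted inside the NC group size
  expect_equal(sum(co$annotations$group == "NC"), 426)
})

test_that("planted composition shifts appear in the truth channel", {
  co <- full_cohort()
  tr <- merge(co$truth, co$annotations, by = "cell")
  tr <- tr[is.na(tr$spikein_kind), ]
  frac <- function(g, sp) mean(tr$subpop[tr$group == g] == sp)
  expect_gt(frac("UT", "C3"), frac("NC", "C3"))
  expect_lt(frac("UT", "C4"), frac("NC", "C4"))
  expect_lt(frac("GCNR", "C2"), frac("NC", "C2"))
  # every non-spike-in cell has exactly one subpop and phase label
  expect_false(anyNA(tr$subpop))
  expect_false(anyNA(tr$phase))
})

test_that("raising a planted log2 fold change raises the planted score", {
  eff0 <- tibble::tibble(group = "UT", subpop = "C1", set = "apoptosis",
                         log2fc = 0)
  eff1 <- eff0; eff1$log2fc <- 1.2
  mean_apoptosis <- function(eff, seed) {
    co <- simulate_cohort(small_config(program_effects = eff, seed = seed))
    tr <- merge(co$truth, co$annotations, by = "cell")
    idx <- tr$group == "UT" & !is.na(tr$subpop) & tr$subpop == "C1"
    sc <- geneset_score(log2_layer(co$counts), co$gene_sets$apoptosis)
    mean(sc$score[match(tr$cell[idx], sc$cell)])
  }
  expect_gt(mean_apoptosis(eff1, 3), mean_apoptosis(eff0, 3))
})

test_that("cohorts round-trip exactly through the plain-text writers", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(unname(as.matrix(back$counts)), unname(as.matrix(co$counts)))
  expect_identical(rownames(back$counts), rownames(co$counts))
  expect_identical(colnames(back$counts), colnames(co$counts))
  expect_equal(nrow(back$truth), nrow(co$counts))
  expect_identical(back$gene_sets, co$gene_sets)
  expect_identical(back$annotations$group, co$annotations$group)
})

test_that("an empty matrix writes a valid MTX header", {
  dir <- withr::local_tempdir()
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0, 5),
                                dimnames = list(NULL, paste0("g", 1:5)))
  write_cohort(list(counts = empty,
                    annotations = tibble::tibble(cell = character()),
                    truth = tibble::tibble(cell = character()),
                    gene_sets = NULL), dir)
  header <- readLines(file.path(dir, "matrix.mtx"), n = 2)
  expect_match(header[1], "MatrixMarket matrix coordinate integer general")
  expect_equal(header[2], "5 0 0")
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(dim(m), c(5, 0))
})

test_that("GMT files round-trip and reject malformed lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(alpha = c("g1", "g2", "g3"), beta = "g9")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
  writeLines("just_one_field", f)
  expect_error(read_gmt(f), "Malformed")
})
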