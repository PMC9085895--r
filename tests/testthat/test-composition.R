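test_that("the worked 60/40 example reproduces Ro/e and chi-square exactly", {
  cells <- data.frame(
    cluster = rep(c("X", "Y"), c(100, 100)),
    group = c(rep("NC", 60), rep("UT", 40), rep("NC", 40), rep("UT", 60))
  )
  roe <- roe_table(cells)
  x_nc <- roe[roe$cluster == "X" & roe$group == "NC", ]
  x_ut <- roe[roe$cluster == "X" & roe$group == "UT", ]
  expect_equal(x_nc$expected, 50)
  expect_equal(x_nc$roe, 1.2)
  expect_equal(x_ut$roe, 0.8)
  expect_equal(x_nc$chisq, 8)
  expect_equal(x_nc$p, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(x_nc$p, 0.004677735, tolerance = 1e-6)
  expect_equal(x_nc$shift, "increased")
  expect_equal(x_ut$shift, "decreased")
})

test_that("uniform and single-group tables give Ro/e of exactly 1", {
  uniform <- expand.grid(cluster = c("A", "B"), group = c("g1", "g2"),
                         rep = 1:25)
  roe <- roe_table(uniform)
  expect_true(all(roe$roe == 1))
  expect_true(all(roe$shift == "unchanged"))
  single <- data.frame(cluster = sample(c("A", "B", "C"), 90, replace = TRUE),
                       group = "only")
  expect_true(all(roe_table(single)$roe == 1))
})

test_that("per-(cluster,group) chi-square matches the textbook implementation", {
  set.seed(8)
  for (rep in 1:20) {
    df <- data.frame(
      cluster = sample(paste0("C", 1:4), 300, replace = TRUE),
      group = sample(c("NC", "UT", "GCR"), 300, replace = TRUE)
    )
    roe <- roe_table(df)
    tab <- table(df$cluster, df$group)
    for (i in seq_len(nrow(roe))) {
      a <- roe$observed[i]
      b <- sum(tab[roe$cluster[i], ]) - a
      c_ <- sum(tab[, roe$group[i]]) - a
      d <- sum(tab) - a - b - c_
      ref <- suppressWarnings(
        chisq.test(matrix(c(a, b, c_, d), 2, byrow = TRUE), correct = FALSE)
      )
      expect_equal(roe$chisq[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(roe$p[i], ref$p.value, tolerance = 1e-10)
    }
    # expected-count-weighted mean Ro/e is exactly 1 within every group
    wm <- tapply(seq_len(nrow(roe)), roe$group, function(idx) {
      sum(roe$expected[idx] * roe$roe[idx]) / sum(roe$expected[idx])
    })
    expect_equal(as.numeric(wm), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("expected counts conserve group totals", {
  df <- data.frame(cluster = sample(paste0("C", 1:5), 400, replace = TRUE),
                   group = sample(c("NC", "UT"), 400, replace = TRUE))
  roe <- roe_table(df)
  expected_by_group <- tapply(roe$expected, roe$group, sum)
  observed_by_group <- table(df$group)
  expect_equal(as.numeric(expected_by_group[names(observed_by_group)]),
               as.numeric(observed_by_group), tolerance = 1e-9)
})

test_that("per-donor Ro/e collapses to the pooled value for one donor per group", {
  df <- data.frame(
    cluster = rep(c("A", "B"), c(120, 80)),
    group = rep(c("NC", "UT"), 100),
    donor = rep(c("NC_d1", "UT_d1"), 100)
  )
  pooled <- roe_table(df)
  per <- roe_per_donor(df)
  merged <- merge(per$by_donor, pooled, by = c("cluster", "group"))
  expect_equal(merged$roe.x, merged$roe.y, tolerance = 1e-12)
  # two donors with identical composition give identical replicates, SEM 0
  df2 <- data.frame(
    cluster = rep(c("A", "B", "A", "B"), c(30, 20, 30, 20)),
    group = "NC",
    donor = rep(c("d1", "d2"), each = 50)
  )
  per2 <- roe_per_donor(df2)
  expect_true(all(per2$summary$sem < 1e-12))
  expect_equal(per2$by_donor$roe[per2$by_donor$donor == "d1"],
               per2$by_donor$roe[per2$by_donor$donor == "d2"])
})

test_that("tidy and glance expose the table and the omnibus test", {
  df <- data.frame(cluster = rep(c("A", "B"), 50),
                   group = rep(c("NC", "UT"), each = 50))
  roe <- roe_table(df)
  td <- tidy(roe)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "roe_result"))
  gl <- glance(roe)
  ref <- suppressWarnings(chisq.test(table(df$cluster, df$group), correct = FALSE))
  expect_equal(gl$omnibus_chisq, unname(ref$statistic))
  expect_equal(gl$omnibus_p, ref$p.value)
})
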