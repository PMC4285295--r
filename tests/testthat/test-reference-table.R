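test_that("reference tables have the advertised shape and per-model counts", {
  cfg <- sample_config(c(2, 2, 2), 20, 500)
  tab <- suppressWarnings(build_reference_table(c("A", "ISO"), SIM_PRIORS, cfg,
                                                n_per_model = 15,
                                                stat_config("full_3pop"),
                                                seed = 81))
  expect_equal(nrow(tab$stats), 30)
  expect_equal(ncol(tab$stats), 52)
  expect_equal(as.vector(table(tab$model)), c(15, 15))
  expect_true(all(is.na(tab$params$F)))
  expect_true(all(!is.na(tab$params$Nm4[tab$model == "A"])))
  expect_true(all(is.na(tab$params$Nm4[tab$model == "ISO"])))

  empty <- build_reference_table("D", SIM_PRIORS, cfg, n_per_model = 0,
                                 stat_config("full_3pop"), seed = 82)
  expect_equal(nrow(empty$stats), 0)
  expect_equal(colnames(empty$stats), stat_names(stat_config("full_3pop")))
})

test_that("table construction is seed-reproducible row by row", {
  cfg <- sample_config(c(2, 2, 2), 15, 500)
  t1 <- build_reference_table("E", SIM_PRIORS, cfg, 10, stat_config("means_only"),
                              seed = 83)
  t2 <- build_reference_table("E", SIM_PRIORS, cfg, 10, stat_config("means_only"),
                              seed = 83)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)
  t3 <- build_reference_table("E", SIM_PRIORS, cfg, 10, stat_config("means_only"),
                              seed = 84)
  expect_false(identical(t1$stats, t3$stats))
})

test_that("tables round-trip through TSV and parquet", {
  cfg <- sample_config(c(2, 2, 2), 15, 500)
  tab <- build_reference_table(c("B", "ISO"), SIM_PRIORS, cfg, 8,
                               stat_config("means_only"), seed = 85)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_reference_table(tab, f)
  re <- read_reference_table(f, stat_config("means_only"))
  expect_equal(re$stats, tab$stats, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.character(re$model), as.character(tab$model))
  expect_equal(re$params, tab$params, tolerance = 1e-12)

  fp <- withr::local_tempfile(fileext = ".parquet")
  write_reference_table(tab, fp, format = "parquet")
  rp <- read_reference_table(fp, stat_config("means_only"), format = "parquet")
  expect_equal(rp$stats, tab$stats, ignore_attr = TRUE)
})

test_that("means-only reduction selects the mean columns of a full table", {
  tab <- iso_table_small()
  mo <- reduce_to_means(tab)
  expect_equal(ncol(mo$stats), 13)
  expect_equal(unname(mo$stats[, "S_total_mean"]),
               unname(tab$stats[, "S_total_mean"]))
  expect_equal(mo$stat_config$id, "means_only")
})

test_that("row subsetting preserves structure and model levels", {
  tab <- noise_table_7(100, seed = 86)
  sub <- tab[tab$model == "C"]
  expect_equal(nrow(sub$stats), 100)
  expect_equal(levels(sub$model), levels(tab$model))
  expect_equal(unique(as.character(sub$model)), "C")
})
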