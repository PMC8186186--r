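test_that("count_matrix validates shapes, duplicates and integrality", {
  m <- matrix(0:5, 2, 3)
  cm <- count_matrix(m, paste0("g", 1:3), paste0("c", 1:2))
  expect_equal(dim(cm), c(2L, 3L))
  expect_error(count_matrix(m, paste0("g", 1:4), paste0("c", 1:2)), "gene_ids")
  expect_error(count_matrix(m, c("g1", "g1", "g2"), paste0("c", 1:2)), "unique")
  expect_error(count_matrix(-m, paste0("g", 1:3), paste0("c", 1:2)),
               "non-negative")
  expect_error(count_matrix(m + 0.5, paste0("g", 1:3), paste0("c", 1:2)),
               "integral")
  expect_error(count_matrix(m, paste0("g", 1:3), paste0("c", 1:2),
                            batch_labels = "b1"), "one label per cell")
})

test_that("mtx triplet directories round-trip through save and load", {
  cm <- tiny_counts(n = 3, G = 4)
  dir <- withr::local_tempdir()
  save_counts_mtx(cm, dir)
  back <- load_counts(dir, "mtx_dir")
  expect_equal(back$values, cm$values)
  expect_equal(back$gene_ids, cm$gene_ids)
  expect_equal(back$cell_ids, cm$cell_ids)
})

test_that("csv loading respects both orientations", {
  cm <- tiny_counts(n = 3, G = 4)
  f1 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(cm$values, check.names = FALSE)
  utils::write.csv(df, f1, row.names = TRUE)
  back <- load_counts(f1, "csv")
  expect_equal(unname(back$values), unname(cm$values))
  # genes-as-rows orientation flag transposes back to cells x genes
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t(cm$values), check.names = FALSE), f2,
                   row.names = TRUE)
  back2 <- load_counts(f2, "csv", genes_as_rows = TRUE)
  expect_equal(unname(back2$values), unname(cm$values))
  expect_equal(back2$gene_ids, cm$gene_ids)
})

test_that("mtx loading errors on missing files and dimension mismatch", {
  cm <- tiny_counts(n = 3, G = 5)
  dir <- withr::local_tempdir()
  save_counts_mtx(cm, dir)
  expect_error(load_counts(file.path(dir, "nope"), "mtx_dir"), "does not exist")
  # 4 gene ids against a 5-gene matrix
  writeLines(cm$gene_ids[1:4], file.path(dir, "genes.tsv"))
  expect_error(load_counts(dir, "mtx_dir"), "4 ids but matrix has 5")
})

test_that("merge_samples stacks cells, intersects genes and sets batches", {
  a <- count_matrix(matrix(1, 10, 3), c("g1", "g2", "g3"), paste0("a", 1:10))
  b <- count_matrix(matrix(2, 20, 3), c("g2", "g3", "g4"), paste0("b", 1:20))
  m <- merge_samples(list(a, b), c("A", "B"))
  expect_equal(dim(m), c(30L, 2L))
  expect_equal(m$gene_ids, c("g2", "g3"))
  expect_equal(m$batch_labels, rep(c("A", "B"), c(10, 20)))
  expect_equal(m$cell_ids[1:10], paste0("a", 1:10))  # order preserved
  # disjoint gene sets error
  d <- count_matrix(matrix(1, 2, 2), c("x1", "x2"), c("d1", "d2"))
  expect_error(merge_samples(list(a, d), c("A", "D")), "empty gene intersection")
  expect_error(merge_samples(list(a), "A"), "at least 2")
})

test_that("duplicate cell ids across samples are suffixed with sample name", {
  a <- count_matrix(matrix(1, 2, 2), c("g1", "g2"), c("c1", "c2"))
  b <- count_matrix(matrix(2, 2, 2), c("g1", "g2"), c("c1", "c2"))
  m <- merge_samples(list(a, b), c("s1", "s2"))
  expect_equal(m$cell_ids, c("c1-s1", "c2-s1", "c1-s2", "c2-s2"))
})

test_that("merge is order-stable: permuting samples permutes blocks only", {
  set.seed(3)
  a <- tiny_counts(4, 3, seed = 11)
  b <- tiny_counts(5, 3, seed = 12)
  b$cell_ids <- paste0("x", 1:5); rownames(b$values) <- b$cell_ids
  m1 <- merge_samples(list(a, b), c("A", "B"))
  m2 <- merge_samples(list(b, a), c("B", "A"))
  expect_equal(m1$values[m1$cell_ids, ], m2$values[m1$cell_ids, ])
})

test_that("latent matrices round-trip as CSV with z-named header", {
  lm <- latent_matrix(matrix(rnorm(6), 2, 3), c("c1", "c2"))
  f <- withr::local_tempfile(fileext = ".csv")
  save_latent(lm, f)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(header, c("cell_id", "z0", "z1", "z2"))
  back <- load_latent(f)
  expect_equal(back$values, lm$values, tolerance = 1e-12)
  expect_equal(back$cell_ids, lm$cell_ids)
  expect_error(latent_matrix(matrix(numeric(0), 0, 0), character(0)),
               "non-empty")
})

test_that("metric reports serialise to JSON and labels to CSV", {
  f <- withr::local_tempfile(fileext = ".json")
  save_metrics(list(ari = 0.5, ami = 0.25), f)
  back <- jsonlite::read_json(f)
  expect_equal(back$ari, 0.5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  save_labels(c(1, 2), c("c1", "c2"), f2)
  expect_equal(utils::read.csv(f2)$label, c(1, 2))
})
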