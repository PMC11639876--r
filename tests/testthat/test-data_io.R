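test_that("dense count reader handles both orientations and validates cells", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 0, 3, 2, 5, 3), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  path <- file.path(dir, "counts.tsv")
  write_counts_dense(m, path)
  cm <- read_counts_dense(path)
  expect_equal(unname(library_sizes(cm)), c(4, 10))
  expect_equal(unclass(cm)[, ], m[, ], ignore_attr = TRUE)

  # transposed file with units_in_rows gives the identical matrix
  tpath <- file.path(dir, "counts_t.tsv")
  df <- data.frame(sample = colnames(m), t(m))
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  cm2 <- read_counts_mtx_safe <- read_counts_dense(tpath, orientation = "units_in_rows")
  expect_equal(unclass(cm2), unclass(cm))

  # CSV dialect is sniffed
  cpath <- file.path(dir, "counts.csv")
  write.table(data.frame(gene = rownames(m), m), cpath, sep = ",",
              quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_counts_dense(cpath)), unclass(cm))

  # duplicate gene id is named in the error
  dpath <- file.path(dir, "dup.tsv")
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t3\t4", "gB\t1\t1"), dpath)
  expect_error(read_counts_dense(dpath), "gA")

  # negative and non-integer cells are located
  npath <- file.path(dir, "neg.tsv")
  writeLines(c("gene\ts1\ts2", "gA\t1\t-2", "gB\t3\t4"), npath)
  expect_error(read_counts_dense(npath), "gA.*s2")
  fpath <- file.path(dir, "frac.tsv")
  writeLines(c("gene\ts1\ts2", "gA\t1\t2.5", "gB\t3\t4"), fpath)
  expect_error(read_counts_dense(fpath), "non-integer")
})

test_that("MTX triplets expand correctly and round-trip", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 4", "3 2 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  cm <- read_counts_mtx(dir)
  expect_equal(unclass(cm),
               matrix(c(4, 0, 0, 0, 0, 7), 3, 2,
                      dimnames = list(c("gA", "gB", "gC"), c("bc1", "bc2"))),
               ignore_attr = TRUE)
  expect_identical(attr(cm, "unit_kind"), "cell")

  # round trip through the writer (gzipped) is the identity
  dir2 <- file.path(dir, "rt")
  write_counts_mtx(cm, dir2, gzip = TRUE)
  expect_true(file.exists(file.path(dir2, "matrix.mtx.gz")))
  expect_equal(unclass(read_counts_mtx(dir2)), unclass(cm))

  # empty triplet list -> zero library sizes rejected
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "matrix.mtx"))
  expect_error(read_counts_mtx(dir), "zero library size")

  # header larger than feature table -> dimension error
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 2 1", "1 1 2"),
             file.path(dir, "matrix.mtx"))
  expect_error(read_counts_mtx(dir), "inconsistent")

  # duplicated feature ids are an error, not deduplicated
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 4", "3 2 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gA", "gC"), file.path(dir, "features.tsv"))
  expect_error(read_counts_mtx(dir), "duplicate gene ids: gA")
})

test_that("spatial reader filters to in-tissue spots and aligns coordinates", {
  dir <- withr::local_tempdir()
  m <- matrix(1:16, 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("bc", 1:4)))
  write_counts_mtx(count_matrix(m, "spot"), dir)
  pos <- data.frame(barcode = paste0("bc", 1:4),
                    in_tissue = c(1, 1, 0, 1),
                    array_row = c(0, 0, 1, 1), array_col = c(0, 1, 0, 1),
                    x = c(10, 110, 10, 110), y = c(10, 10, 110, 110))
  write.table(pos, file.path(dir, "tissue_positions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  sp <- read_spatial(dir)
  expect_equal(colnames(sp$counts), c("bc1", "bc2", "bc4"))
  expect_identical(attr(sp$counts, "unit_kind"), "spot")
  # grid coordinates pass through verbatim
  expect_equal(sp$coords$row[match(c("bc1", "bc2", "bc4"), sp$coords$unit_id)],
               c(0L, 0L, 1L))
  expect_equal(sp$coords$col[match(c("bc1", "bc2", "bc4"), sp$coords$unit_id)],
               c(0L, 1L, 1L))

  # headerless dialect reads identically
  write.table(pos, file.path(dir, "tissue_positions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  sp2 <- read_spatial(dir)
  expect_equal(unclass(sp2$counts), unclass(sp$counts))

  # a counts barcode missing from positions is named
  write.table(pos[-2, ], file.path(dir, "tissue_positions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  expect_error(read_spatial(dir), "bc2")
})

test_that("prediction tables label by argmax with canonical-order ties and round-trip", {
  P <- cbind(u1 = c(0.1, 0.2, 0.3, 0.4), u2 = rep(0.25, 4),
             u3 = c(0.55, 0.3, 0.1, 0.05))
  rownames(P) <- subtype_levels()
  preds <- ovsubtype:::probs_to_predictions(P, mixed_threshold = 0.2)
  expect_equal(preds$label, c("P", "D", "D"))   # tie -> first in D,I,M,P order
  expect_equal(preds$mixed, c(TRUE, TRUE, TRUE))
  preds2 <- ovsubtype:::probs_to_predictions(cbind(u = c(1, 0, 0, 0)), 0.2)
  expect_equal(preds2$label, "D")
  expect_false(preds2$mixed)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  for (pc in paste0("p_", subtype_levels()))
    expect_equal(back[[pc]], preds[[pc]], tolerance = 1e-6)
  expect_equal(back$label, preds$label)
  expect_equal(back$mixed, preds$mixed)
})

test_that("label tables validate subtype codes and round-trip", {
  lt <- label_table(c("a", "b"), c("D", "M"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lt, path)
  expect_equal(read_labels(path), lt, ignore_attr = TRUE)
  expect_error(label_table(c("a", "b"), c("D", "X")), "invalid subtype")
  expect_error(label_table(c("a", "a"), c("D", "M")), "duplicate")
})
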