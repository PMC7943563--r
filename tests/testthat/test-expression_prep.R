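test_that("TSV expression files round-trip and duplicate genes collapse by mean", {
  m <- toy_matrix(matrix(c(1.5, 2.25, 3, 4.125), 2), genes = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expression_matrix(m), path)
  back <- read_expression(path)
  expect_equal(back$values, m)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "a\t1", "a\t3", "b\t5"), dup)
  expect_warning(got <- read_expression(dup), "duplicated gene")
  expect_equal(got$values["a", "s1"], 2)

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "a\t1\t2", "b\t1"), ragged)
  expect_error(read_expression(ragged), "line 3",
               class = "nescore_format_error")
})

test_that("GCT round-trips and dimension mismatches are rejected", {
  m <- toy_matrix(matrix(1:6 / 2, 3), genes = c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".gct")
  write_expression(expression_matrix(m), path, format = "gct")
  expect_equal(read_expression(path)$values, m)

  bad <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t2", "Name\tDescription\ts1\ts2",
               "a\ta\t1\t2", "b\tb\t3\t4"), bad)
  expect_error(read_expression(bad), "dimensions",
               class = "nescore_format_error")
})

test_that("quantile normalization matches the hand-worked example and its contract", {
  m <- toy_matrix(cbind(c(1, 2, 3), c(6, 4, 2)))
  qn <- quantile_normalize(expression_matrix(m))
  # frozen oracle: sorted-row means are (1.5, 3, 4.5)
  expect_equal(unname(qn$values[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn$values[, 2]), c(4.5, 3, 1.5))

  # identical columns unchanged; single column unchanged
  same <- toy_matrix(cbind(c(2, 1, 5), c(2, 1, 5)))
  expect_equal(quantile_normalize(expression_matrix(same))$values, same)
  single <- toy_matrix(cbind(c(3, 1, 2)))
  expect_equal(quantile_normalize(expression_matrix(single))$values, single)

  # ties share the mean of the reference values at their tied ranks
  tied <- toy_matrix(cbind(c(1, 1, 5), c(2, 4, 6)))
  qt <- quantile_normalize(expression_matrix(tied))
  ref <- unname(rowMeans(apply(tied, 2, sort)))
  expect_equal(unname(qt$values[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalization is idempotent, rank-preserving, and matches limma on tie-free data", {
  withr::with_seed(11, {
    m <- toy_matrix(matrix(rnorm(60), 10))
    once <- quantile_normalize(expression_matrix(m))
    twice <- quantile_normalize(once)
    expect_equal(twice$values, once$values, tolerance = 1e-12)
    for (j in seq_len(ncol(m))) {
      expect_equal(order(once$values[, j]), order(m[, j]))
    }
    skip_if_not_installed("limma")
    expect_equal(unname(once$values), unname(limma::normalizeQuantiles(m)),
                 tolerance = 1e-12)
  })
})

test_that("log2 transform applies the offset and refuses invalid input", {
  m <- expression_matrix(toy_matrix(cbind(c(0, 3, 1023))), scale = "linear")
  lg <- log2_transform(m, offset = 1)
  expect_equal(unname(lg$values[, 1]), c(0, 2, 10))
  expect_equal(lg$scale, "log2")
  expect_error(log2_transform(lg), "already log2",
               class = "nescore_validation_error")
  neg <- expression_matrix(toy_matrix(cbind(c(-1, 2, 3))), scale = "linear")
  expect_error(log2_transform(neg), class = "nescore_validation_error")
})

test_that("library-size normalization equalizes totals at the median", {
  m <- toy_matrix(matrix(c(100, 0, 0, 0, 150, 50, 120, 90, 90), 3))
  # totals 100, 200, 300 -> target 200, factors 2, 1, 2/3
  out <- library_size_normalize(expression_matrix(m, scale = "linear"))
  expect_equal(unname(colSums(out$values)), c(200, 200, 200))
  expect_equal(unname(out$values[, 1]), c(200, 0, 0))

  single <- expression_matrix(toy_matrix(cbind(c(1, 2, 3))), scale = "linear")
  expect_equal(library_size_normalize(single)$values, single$values)

  zero <- expression_matrix(toy_matrix(cbind(c(1, 1), c(0, 0))),
                            scale = "linear")
  expect_error(library_size_normalize(zero), "s2",
               class = "nescore_validation_error")
})

test_that("z-score standardization centers/scales with the n-1 convention", {
  m <- expression_matrix(toy_matrix(cbind(a = c(1, 2, 3))))
  z <- zscore_standardize(m, "per_sample")
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))

  const <- expression_matrix(toy_matrix(cbind(a = c(5, 5, 5), b = c(1, 2, 3))))
  expect_warning(zc <- zscore_standardize(const, "per_sample"), "constant")
  expect_equal(unname(zc$values[, "a"]), c(0, 0, 0))

  # recomposition inverts the transform
  withr::with_seed(3, {
    x <- toy_matrix(matrix(rnorm(40, 5, 2), 8))
    z2 <- zscore_standardize(expression_matrix(x), "per_sample")
    rebuilt <- sweep(sweep(z2$values, 2, apply(x, 2, sd), `*`),
                     2, colMeans(x), `+`)
    expect_equal(rebuilt, x, tolerance = 1e-12)
  })
})

test_that("z-scoring a sample does not change its NE score (affine link)", {
  bundle <- default_bundle()
  sig <- bundle$signature
  raw <- bundle$expr$values[, 1]
  z <- (raw - mean(raw)) / sd(raw)
  expect_equal(compute_ne_score(z, sig)$ne_score,
               compute_ne_score(raw, sig)$ne_score)
})

test_that("cluster averaging drops small clusters and min-max scales per gene", {
  genes <- c("up", "flat")
  cells <- paste0("c", 1:25)
  cl <- c(rep("A", 10), rep("B", 10), rep("tiny", 5))
  v <- rbind(up = c(rep(1, 10), rep(3, 10), rep(99, 5)),
             flat = rep(2, 25))
  colnames(v) <- cells
  expr <- expression_matrix(v, scale = "log2")
  expect_warning(
    expect_message(out <- cluster_average_minmax(expr, stats::setNames(cl, cells)),
                   "tiny"),
    "constant")
  expect_equal(sort(colnames(out$values)), c("A", "B"))
  expect_equal(unname(out$values["up", c("A", "B")]), c(0, 1))
  expect_equal(unname(out$values["flat", ]), c(0, 0))

  # three clusters with means 1, 2, 3 -> 0, 0.5, 1
  v3 <- matrix(rep(c(1, 2, 3), each = 10), nrow = 1,
               dimnames = list("g", paste0("c", 1:30)))
  cl3 <- stats::setNames(rep(c("A", "B", "C"), each = 10), colnames(v3))
  out3 <- cluster_average_minmax(expression_matrix(v3), cl3)
  expect_equal(unname(out3$values[1, c("A", "B", "C")]), c(0, 0.5, 1))

  expect_error(cluster_average_minmax(expr, stats::setNames(rep("A", 25), cells)),
               class = "nescore_validation_error")
})
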