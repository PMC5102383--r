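test_that("depth normalisation rescales every sample to the target", {
  m <- toy_matrix(matrix(c(5e6, 5e6, 2.5e6, 2.5e6), 2, 2))
  norm <- normalize_counts(m)
  expect_equal(unname(colSums(norm$values)), c(1e7, 1e7))
  # a sample already at the target is unchanged
  expect_equal(norm$values[, 1], m$values[, 1], ignore_attr = TRUE)
  # count 5 in a sample totalling 5e6 doubles
  m2 <- toy_matrix(matrix(c(5, 5e6 - 5), 2, 1))
  expect_equal(normalize_counts(m2)$values[1, 1], 10)

  set.seed(1)
  m3 <- toy_matrix(matrix(rpois(12, 50), 4, 3))
  expect_equal(unname(colSums(normalize_counts(m3)$values)), rep(1e7, 3))

  m4 <- toy_matrix(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(normalize_counts(m4), "zero total count: s02")
})

test_that("expression filter keeps genes with mean strictly above threshold", {
  vals <- rbind(c(0.1, 0.1), c(2, 2), c(2.01, 2.01), c(50, 50), c(0, 9),
                c(1.99, 1.99))
  m <- toy_matrix(vals, stage = "normalized")
  kept <- filter_expressed(m)
  expect_equal(unname(rownames(kept$values)), c("g03", "g04", "g05"))
  expect_warning(filter_expressed(m, min_mean = 100), "no genes")
})

test_that("log2 transform applies the pseudocount", {
  m <- toy_matrix(matrix(c(0, 3, 1023, 7), 2, 2), stage = "normalized")
  lg <- log2_transform(m)
  expect_equal(lg$values[1, 1], 0)       # log2(0 + 1)
  expect_equal(lg$values[2, 1], 2)       # log2(3 + 1)
  expect_equal(lg$values[1, 2], 10)      # log2(1023 + 1) = log2(1024)
  expect_equal(lg$stage, "log2")
})

test_that("stage tags enforce the pipeline order", {
  raw <- toy_matrix(matrix(1:4, 2, 2))
  expect_error(filter_expressed(raw), "stage")
  expect_error(log2_transform(raw), "stage")
  expect_error(batch_adjust(raw, c("A", "B")), "stage")
  norm <- normalize_counts(raw)
  expect_error(normalize_counts(norm), "stage")
})

test_that("normalise-then-filter commutes with sample reordering", {
  set.seed(8)
  m <- toy_matrix(matrix(rpois(60, 20), 10, 6))
  perm <- c(4, 1, 6, 2, 5, 3)
  direct <- filter_expressed(normalize_counts(m), min_mean = 2e6 / 10)
  swapped <- filter_expressed(normalize_counts(
    toy_matrix(m$values[, perm], samples = colnames(m$values)[perm])),
    min_mean = 2e6 / 10)
  expect_equal(swapped$values, direct$values[, perm])
})

test_that("single-batch adjustment is the identity", {
  set.seed(2)
  m <- toy_matrix(matrix(rnorm(40, 8), 8, 5), stage = "log2")
  out <- batch_adjust(m, rep("only", 5))
  expect_equal(out$matrix$values, m$values)
  expect_equal(out$matrix$stage, "batch_adjusted")
})

test_that("a pure location shift between batches is removed", {
  set.seed(3)
  G <- 200
  n1 <- 15
  # per-gene noise standardised to unit sample sd so gene scales are equal
  noise <- t(apply(matrix(rnorm(G * n1), G, n1), 1,
                   function(e) as.numeric(scale(e))))
  A <- matrix(rnorm(G, 8, 2), G, n1) + noise
  Y <- cbind(A, A + 3)
  dimnames(Y) <- list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:(2 * n1)))
  batch <- rep(c("A", "B"), each = n1)
  adj <- batch_adjust(expression_matrix(Y, "log2"), batch)
  diffs <- abs(rowMeans(adj$matrix$values[, batch == "A"]) -
               rowMeans(adj$matrix$values[, batch == "B"]))
  expect_lt(max(diffs), 0.05)
  # grand mean preserved per gene
  expect_lt(max(abs(rowMeans(adj$matrix$values) - rowMeans(Y))), 1e-6)
  expect_true(all(adj$model$delta2_star > 0))
})

test_that("null batch structure leaves the matrix nearly unchanged", {
  set.seed(5)
  G <- 150
  n1 <- 150
  Y <- matrix(rnorm(G * 2 * n1, 8, 1), G, 2 * n1,
              dimnames = list(sprintf("g%03d", 1:G),
                              sprintf("t%03d", 1:(2 * n1))))
  batch <- rep(c("A", "B"), each = n1)
  adj <- batch_adjust(expression_matrix(Y, "log2"), batch)
  expect_lt(mean(abs(adj$matrix$values - Y)), 0.05)
  expect_lt(max(abs(rowMeans(adj$matrix$values) - rowMeans(Y))), 1e-6)
})

test_that("batch adjustment agrees with the reference implementation", {
  set.seed(7)
  G <- 120
  Y <- matrix(rnorm(G * 30, 8, 1), G, 30,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:30)))
  batch <- rep(c("A", "B", "C"), each = 10)
  Y[, batch == "B"] <- Y[, batch == "B"] + 1.5
  Y[, batch == "C"] <- Y[, batch == "C"] * 1.2
  ours <- batch_adjust(expression_matrix(Y, "log2"), batch)$matrix$values
  ref <- suppressMessages(sva::ComBat(Y, batch = factor(batch)))
  # identical up to the per-gene grand-mean restoration convention
  expect_lt(max(abs((ours - rowMeans(ours)) - (ref - rowMeans(ref)))), 0.02)
  expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
})

test_that("degenerate batches are rejected", {
  m <- toy_matrix(matrix(rnorm(30, 8), 6, 5), stage = "log2")
  expect_error(batch_adjust(m, c("A", "A", "A", "A", "B")), "degenerate")
  expect_error(batch_adjust(m, c("A", "B")), "one label per sample")
})

test_that("expression matrices round-trip through TSV with their stage", {
  set.seed(11)
  m <- toy_matrix(matrix(rnorm(12, 5), 4, 3), stage = "normalized")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(m, path)
  back <- read_expression_tsv(path)
  expect_equal(back$stage, "normalized")
  expect_equal(back$values, m$values, tolerance = 1e-12)
})
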