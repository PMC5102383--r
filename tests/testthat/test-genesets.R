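test_that("GMT files parse and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1\tG2", "S2\tother\tG3\tG4\tG5"), path)
  col <- read_gmt(path)
  expect_equal(col$sets$S1, c("G1", "G2"))
  expect_equal(col$sets$S2, c("G3", "G4", "G5"))

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, out)
  back <- read_gmt(out)
  expect_equal(lapply(back$sets, sort), lapply(col$sets, sort))

  writeLines("S1\tdesc\tG1\tG1\tG2", path)
  expect_warning(col2 <- read_gmt(path), "duplicate")
  expect_equal(col2$sets$S1, c("G1", "G2"))

  writeLines("BAD\tonly-two-fields", path)
  expect_error(read_gmt(path), "line 1")

  writeLines(character(), path)
  expect_warning(empty <- read_gmt(path), "empty")
  expect_length(empty$sets, 0)
})

test_that("changed-gene calling thresholds the SY minus non-SY difference", {
  classes <- rep(c("SY", "non-SY"), each = 3)
  base <- matrix(0, 6, 6)
  deltas <- c(0, 0.3, -0.3, 0.29, -1.2, 2)
  vals <- base + outer(deltas, as.numeric(classes == "SY"))
  m <- toy_matrix(vals, stage = "log2")
  ch <- call_changed_genes(m, classes)
  expect_setequal(ch$up, c("g02", "g06"))   # 0.3 boundary is inclusive
  expect_setequal(ch$down, c("g03", "g05"))
  expect_equal(ch$universe, rownames(m$values))

  flat <- call_changed_genes(toy_matrix(base, stage = "log2"), classes)
  expect_length(flat$up, 0)
  expect_length(flat$down, 0)
})

test_that("enrichment p-values equal direct hypergeometric tail summation", {
  universe <- sprintf("G%03d", 1:200)
  planted <- universe[1:20]
  collection <- structure(list(name = "toy",
                               sets = list(PLANTED = planted,
                                           RANDOM = universe[51:90],
                                           ABSENT = c("X1", "X2")),
                               descriptions = c(PLANTED = "d", RANDOM = "d",
                                                ABSENT = "d")),
                          class = "gene_set_collection")
  expect_warning(res <- enrich(planted, character(), universe, collection,
                               fdr = Inf), "ABSENT")
  top <- res[1, ]
  expect_equal(top$set, "PLANTED")
  expect_equal(top$direction, "up")
  expect_equal(top$n_overlap, 20)
  expect_lt(top$p, 1e-4)
  expect_equal(top$p, hyper_tail_oracle(20, 20, 200, 20), tolerance = 1e-12)
  # every reported p matches the oracle
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 hyper_tail_oracle(res$n_overlap[i], res$n_set_in_universe[i],
                                   200, res$n_changed[i]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment handles empty inputs and is order-invariant", {
  universe <- sprintf("G%03d", 1:50)
  collection <- structure(list(name = "toy",
                               sets = list(S = universe[1:10]),
                               descriptions = c(S = "d")),
                          class = "gene_set_collection")
  none <- enrich(character(), character(), universe, collection)
  expect_equal(nrow(none), 0)
  expect_error(enrich("G001", character(), character(), collection),
               "empty universe")

  up <- universe[c(3, 1, 7)]
  a <- enrich(up, character(), universe, collection, fdr = Inf)
  b <- enrich(rev(up), character(), rev(universe), collection, fdr = Inf)
  expect_equal(a$p, b$p)
})

test_that("cumulative set comparison detects a planted shift", {
  set.seed(40)
  classes <- rep(c("SY", "non-SY"), c(5, 8))
  G <- 60
  vals <- matrix(rnorm(G * 13, 0, 0.3), G, 13)
  members <- sprintf("g%02d", 1:30)
  vals[1:30, classes == "SY"] <- vals[1:30, classes == "SY"] - 1
  m <- toy_matrix(vals, stage = "log2")
  out <- cumulative_set_test(m, classes, members)
  expect_lt(out$test$p, 0.01)
  # SY curve is left-shifted: at the non-SY median the SY ECDF is higher
  med <- median(out$means$mean_nonsy)
  expect_gt(out$ecdf_sy(med), out$ecdf_nonsy(med))
  # ECDF sanity: non-decreasing, reaching 1
  xs <- sort(c(out$means$mean_sy, out$means$mean_nonsy))
  expect_true(all(diff(out$ecdf_sy(xs)) >= 0))
  expect_equal(out$ecdf_sy(max(xs)), 1)
  expect_equal(out$ecdf_nonsy(max(xs)), 1)
})

test_that("cumulative set comparison is null on identical groups", {
  classes <- rep(c("SY", "non-SY"), c(4, 4))
  vals <- matrix(rep(1:10, 8), 10, 8)
  m <- toy_matrix(vals, stage = "log2")
  out <- cumulative_set_test(m, classes, rownames(m$values))
  expect_equal(out$test$p, 1)
  expect_equal(out$ecdf_sy(1:10), out$ecdf_nonsy(1:10))
  expect_error(cumulative_set_test(m, classes, rownames(m$values)[1:3]),
               "insufficient set")
})

test_that("set-level shift detection has high power at one log2 unit", {
  hits <- 0
  for (rep in 1:10) {
    set.seed(400 + rep)
    classes <- rep(c("SY", "non-SY"), c(6, 10))
    vals <- matrix(rnorm(50 * 16, 0, 0.5), 50, 16)
    vals[1:30, classes == "SY"] <- vals[1:30, classes == "SY"] - 1
    m <- toy_matrix(vals, stage = "log2")
    out <- cumulative_set_test(m, classes, sprintf("g%02d", 1:30))
    hits <- hits + (out$test$p < 0.05)
  }
  expect_gte(hits, 9)
})
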