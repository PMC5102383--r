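test_that("per-gene OLS matches the closed-form oracle", {
  age <- c(20, 35, 50, 65)
  y <- c(3.1, 4.0, 4.4, 6.0)
  m <- toy_matrix(rbind(y, 0.1 * age + 5), stage = "log2",
                  genes = c("gA", "gExact"))
  fits <- fit_gene_models(m, age)

  oracle <- ols_oracle(age, y)
  expect_equal(fits$beta[1], oracle$slope)
  expect_equal(fits$s2[1], sum(oracle$residuals^2) / 2)
  expect_equal(unique(fits$v), solve(crossprod(cbind(1, age)))[2, 2])
  expect_equal(fits$df, c(2L, 2L))

  # the exactly-linear gene is flagged untestable
  expect_equal(fits$beta[2], 0.1)
  expect_true(fits$zero_var[2])
  expect_false(fits$zero_var[1])
})

test_that("gene fits are invariant to sample order", {
  set.seed(13)
  m <- toy_matrix(matrix(rnorm(50, 8), 5, 10), stage = "log2")
  age <- sample(20:80, 10)
  perm <- sample(10)
  f1 <- fit_gene_models(m, age)
  f2 <- fit_gene_models(toy_matrix(m$values[, perm],
                                   samples = colnames(m$values)[perm],
                                   stage = "log2"), age[perm])
  expect_equal(f1, f2)
})

test_that("singular or undersized designs are rejected", {
  m <- toy_matrix(matrix(rnorm(20, 8), 4, 5), stage = "log2")
  expect_error(fit_gene_models(m, rep(3, 5)), "singular")
  m2 <- toy_matrix(matrix(rnorm(4, 8), 2, 2), stage = "log2")
  expect_error(fit_gene_models(m2, 1:2), "3 samples")
})

test_that("identical variances give a degenerate prior; scaling is equivariant", {
  fits <- structure(data.frame(gene_id = as.character(1:20), beta = 0, v = 1,
                               s2 = 0.7, df = 10L, zero_var = FALSE),
                    class = c("gene_fits", "data.frame"))
  pr <- estimate_prior(fits)
  expect_equal(pr$d0, Inf)
  expect_equal(pr$s02, 0.7, tolerance = 1e-6)

  set.seed(14)
  fits2 <- fits
  fits2$s2 <- 0.5 * 4 / rchisq(20, 4)
  pr2 <- estimate_prior(fits2)
  fits3 <- fits2
  fits3$s2 <- fits2$s2 * 2
  pr3 <- estimate_prior(fits3)
  expect_equal(pr3$d0, pr2$d0)
  expect_equal(pr3$s02, 2 * pr2$s02)

  expect_error(estimate_prior(fits[1:5, ]), "insufficient genes")
})

test_that("prior estimation recovers simulated hyperparameters and matches limma", {
  set.seed(10)
  G <- 5000
  d0 <- 4
  s02 <- 0.25
  df <- 20L
  s2 <- (s02 * d0 / rchisq(G, d0)) * rchisq(G, df) / df
  fits <- structure(data.frame(gene_id = as.character(seq_len(G)), beta = 0,
                               v = 1, s2 = s2, df = df, zero_var = FALSE),
                    class = c("gene_fits", "data.frame"))
  pr <- estimate_prior(fits)
  expect_lt(abs(pr$d0 - d0) / d0, 0.2)
  sq <- limma::squeezeVar(s2, df)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s02, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t reduces to the ordinary t as the prior df vanishes", {
  set.seed(15)
  m <- toy_matrix(matrix(rnorm(120, 8), 12, 10), stage = "log2")
  age <- seq(20, 65, by = 5)
  fits <- fit_gene_models(m, age)
  tiny <- structure(list(d0 = 1e-9, s02 = 1), class = "moderation_prior")
  res <- moderated_test(fits, tiny)
  ordinary <- fits$beta / sqrt(fits$v * fits$s2)
  expect_equal(res$t, ordinary, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-abs(ordinary), df = fits$df), tolerance = 1e-5)
})

test_that("moderated test handles zero effects and flagged genes", {
  fits <- structure(data.frame(gene_id = c("a", "b"), beta = c(0, 1),
                               v = 0.1, s2 = c(0.5, 0), df = 8L,
                               zero_var = c(FALSE, TRUE)),
                    class = c("gene_fits", "data.frame"))
  pr <- structure(list(d0 = 4, s02 = 0.5), class = "moderation_prior")
  res <- moderated_test(fits, pr)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(is.na(res$p[2]))
  # shrinkage direction: observed s2 below s02 is pulled up, so the
  # moderated statistic is smaller than the ordinary one
  fits2 <- structure(data.frame(gene_id = "c", beta = 1, v = 0.1, s2 = 0.1,
                                df = 8L, zero_var = FALSE),
                     class = c("gene_fits", "data.frame"))
  res2 <- moderated_test(fits2, pr)
  expect_lt(abs(res2$t), abs(1 / sqrt(0.1 * 0.1)))
})

test_that("BH adjustment equals the hand step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(16)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p))
  # permutation invariance
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_oracle(p)[perm])
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "invalid p")
  expect_error(bh_adjust(c(0.5, 1.2)), "invalid p")
})

test_that("age-gene detection recovers injected genes and splits by sign", {
  cfg <- sim_config(n_subjects = 80, n_genes = 600, n_age_genes = 40,
                    n_sy_genes = 0, seed = 17)
  sim <- simulate_study(cfg)
  expr <- preprocess_counts(sim$matrix, batches = sim$cohort$batch)
  res <- detect_age_genes(expr, sim$cohort$age)
  hits <- c(res$up, res$down)
  expect_gte(mean(sim$truth$age_genes$gene_id %in% hits), 0.8)
  expect_length(intersect(res$up, res$down), 0)
  detected <- res$table$gene_id[!is.na(res$table$fdr) & res$table$fdr < 0.01]
  expect_setequal(hits, detected)
  # directions match the injected signs
  found <- sim$truth$age_genes[sim$truth$age_genes$gene_id %in% hits, ]
  expect_true(all((found$gene_id %in% res$up) == (found$sign > 0)))
})

test_that("age residualization removes linear age trends", {
  age <- c(20, 30, 50, 70)
  m <- toy_matrix(rbind(0.2 * age + 1, c(5, 3, 8, 2)), stage = "log2")
  r <- residualize_on_age(m, age)
  expect_equal(unname(r$values[1, ]), rep(0, 4))
  oracle <- ols_oracle(age, c(5, 3, 8, 2))
  expect_equal(unname(r$values[2, ]), oracle$residuals)
  expect_equal(unname(rowSums(r$values)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(drop(r$values %*% age)), c(0, 0), tolerance = 1e-8)
})

test_that("SY label swap flips coefficients but not p-values", {
  sim <- small_study(seed = 18)
  expr <- preprocess_counts(sim$matrix, batches = sim$cohort$batch)
  classes <- ifelse(sim$cohort$subject_id %in% sim$truth$true_sy_subjects,
                    "SY", "non-SY")
  a <- detect_sy_genes(expr, sim$cohort$age, classes)
  swapped <- ifelse(classes == "SY", "non-SY", "SY")
  b <- detect_sy_genes(expr, sim$cohort$age, swapped)
  ta <- a$table[order(a$table$gene_id), ]
  tb <- b$table[order(b$table$gene_id), ]
  expect_equal(ta$beta, -tb$beta)
  expect_equal(ta$p, tb$p, tolerance = 1e-12)
  expect_setequal(a$up, b$down)
})

test_that("SY detection is invariant to gene-independent age trends", {
  sim <- small_study(seed = 19)
  expr <- preprocess_counts(sim$matrix, batches = sim$cohort$batch)
  classes <- ifelse(sim$cohort$subject_id %in% sim$truth$true_sy_subjects,
                    "SY", "non-SY")
  a <- detect_sy_genes(expr, sim$cohort$age, classes)
  shifted <- expression_matrix(
    sweep(expr$values, 2L, 0.31 * sim$cohort$age - 4, "+"), expr$stage)
  b <- detect_sy_genes(shifted, sim$cohort$age, classes)
  expect_equal(a$table$p, b$table$p, tolerance = 1e-9)
})

test_that("SY detection needs both groups", {
  sim <- small_study(seed = 20)
  expr <- preprocess_counts(sim$matrix, batches = sim$cohort$batch)
  classes <- rep("non-SY", nrow(sim$cohort))
  classes[1] <- "SY"
  expect_error(detect_sy_genes(expr, sim$cohort$age, classes),
               "insufficient group")
})

test_that("moderated pipeline matches limma on shared data", {
  set.seed(23)
  G <- 400
  n <- 30
  Y <- matrix(rnorm(G * n, 8, 1), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  age <- sample(20:80, n, replace = TRUE)
  fits <- fit_gene_models(expression_matrix(Y, "log2"), age)
  res <- moderated_test(fits, estimate_prior(fits))
  lf <- limma::eBayes(limma::lmFit(Y, cbind(1, age)))
  expect_equal(res$t, lf$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  # prior-df root finders stop at slightly different points, which moves the
  # reference df and hence p in the 5th decimal
  expect_equal(res$p, lf$p.value[, 2], tolerance = 1e-4, ignore_attr = TRUE)
})
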