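#' Per-gene ordinary least squares against one covariate
#'
#' Fits, for every gene, expression ~ intercept + covariate by OLS. The
#' covariate is either numeric (e.g. chronological age, giving a log2 slope
#' per year) or a binary group indicator (giving a log2 group difference).
#'
#' @param m an \code{ExpressionMatrix} at stage \code{"log2"} or
#'   \code{"batch_adjusted"}.
#' @param covariate numeric vector, one value per sample; must not be
#'   constant.
#' @return A data frame of class \code{"gene_fits"} with one row per gene:
#'   \code{gene_id}, \code{beta} (covariate coefficient), \code{v} (unscaled
#'   coefficient variance, the covariate's diagonal element of (X'X)^-1),
#'   \code{s2} (residual variance), \code{df} (residual degrees of freedom),
#'   \code{zero_var} (TRUE when the gene fits exactly, s2 = 0; such genes are
#'   excluded from prior estimation and reported untestable).
#' @export
fit_gene_models <- function(m, covariate) {
  assert_stage(m, c("log2", "batch_adjusted"), "fit_gene_models")
  Y <- m$values
  n <- ncol(Y)
  if (length(covariate) != n) stop("'covariate' must have one value per sample")
  if (n < 3L) stop("need at least 3 samples")
  if (length(unique(covariate)) < 2L) {
    stop("singular design: covariate is constant")
  }
  X <- cbind(1, covariate)
  fit <- stats::lm.fit(X, t(Y))
  beta <- fit$coefficients[2L, ]
  res <- fit$residuals                     # samples x genes
  df <- n - 2L
  s2 <- colSums(res^2) / df
  v <- solve(crossprod(X))[2L, 2L]
  # relative tolerance for "fits exactly": scale by the gene's total variation
  tot <- rowSums((Y - rowMeans(Y))^2) / max(1, n - 1)
  zero <- s2 <= pmax(tot, 1) * 1e-12
  structure(data.frame(gene_id = rownames(Y), beta = unname(beta),
                       v = v, s2 = unname(s2), df = df,
                       zero_var = unname(zero), stringsAsFactors = FALSE),
            class = c("gene_fits", "data.frame"))
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  stopifnot(is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Estimate the variance-moderation prior across genes
#'
#' Models the per-gene residual variances as draws from a scaled inverse
#' chi-square prior with d0 degrees of freedom and scale s0^2, and estimates
#' (d0, s0^2) by moment matching on the log variances: with
#' e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2), the excess dispersion of
#' e_g over what finite d_g alone explains determines trigamma(d0/2), which
#' is inverted numerically. When the observed dispersion does not exceed the
#' sampling contribution the prior is degenerate: d0 = Inf and s0^2 =
#' exp(mean(e_g)) (complete pooling).
#'
#' @param fits a \code{gene_fits} data frame; genes flagged \code{zero_var}
#'   are excluded.
#' @return A list of class \code{"moderation_prior"}: \code{d0}, \code{s02}.
#' @export
estimate_prior <- function(fits) {
  use <- fits[!fits$zero_var & fits$s2 > 0, , drop = FALSE]
  G <- nrow(use)
  if (G < 10L) stop("insufficient genes: need >= 10 with positive residual variance")
  dg <- use$df
  e <- log(use$s2) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(dg / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    # log-variances no more dispersed than sampling alone explains:
    # complete pooling onto the average variance
    d0 <- Inf
    s02 <- mean(use$s2)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s02 = s02), class = "moderation_prior")
}

#' Moderated t-tests with empirical-Bayes variance shrinkage
#'
#' Shrinks each gene's residual variance towards the prior scale:
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d), the posterior mean of the
#' variance under the scaled inverse chi-square prior. The moderated t is
#' beta / sqrt(v s_tilde^2) on d0 + d degrees of freedom (standard normal in
#' the complete-pooling limit d0 = Inf); at d0 = 0 it reduces to the ordinary
#' t-test. Two-sided p-values throughout.
#'
#' @param fits a \code{gene_fits} data frame.
#' @param prior a \code{moderation_prior}.
#' @return A data frame with one row per gene: \code{gene_id}, \code{beta},
#'   \code{fc} (2^beta), \code{t}, \code{p}, \code{direction} ("up"/"down").
#'   Genes flagged \code{zero_var} get NA statistics (untestable).
#' @export
moderated_test <- function(fits, prior) {
  stopifnot(inherits(prior, "moderation_prior"),
            prior$d0 > 0, prior$s02 > 0)
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s02, nrow(fits))
  } else {
    (d0 * prior$s02 + fits$df * fits$s2) / (d0 + fits$df)
  }
  tstat <- fits$beta / sqrt(fits$v * s2_post)
  p <- 2 * stats::pt(-abs(tstat), df = d0 + fits$df)
  tstat[fits$zero_var] <- NA_real_
  p[fits$zero_var] <- NA_real_
  data.frame(gene_id = fits$gene_id, beta = fits$beta, fc = 2^fits$beta,
             t = tstat, p = p,
             direction = ifelse(fits$beta >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in (0, 1]; NAs pass through.
#' @return Adjusted p-values (FDR q-values) in the input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] <= 0 | pvalues[ok] > 1)) {
    stop("invalid p-values: must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Detect genes whose expression changes with chronological age
#'
#' Regresses each gene on chronological age, applies moderated t-tests and
#' Benjamini-Hochberg adjustment, and reports genes with adjusted p below
#' \code{fdr}, split by direction.
#'
#' @param m preprocessed \code{ExpressionMatrix} (stage \code{"log2"} or
#'   \code{"batch_adjusted"}).
#' @param ages chronological ages, one per sample.
#' @param fdr FDR threshold on the adjusted p (default 0.01).
#' @return A list: \code{up}, \code{down} (gene id vectors), \code{table}
#'   (full results sorted by p: gene_id, beta, fc, t, p, fdr, direction).
#' @export
detect_age_genes <- function(m, ages, fdr = 0.01) {
  fits <- fit_gene_models(m, ages)
  res <- moderated_test(fits, estimate_prior(fits))
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p), ]
  hit <- !is.na(res$fdr) & res$fdr < fdr
  list(up = res$gene_id[hit & res$direction == "up"],
       down = res$gene_id[hit & res$direction == "down"],
       table = res)
}

#' Remove the chronological-age trend from every gene
#'
#' Per gene, OLS of expression on age over the provided samples; the values
#' are replaced by the residuals ("relative expression"), so downstream group
#' comparisons are free of shared ageing effects.
#'
#' @inheritParams detect_age_genes
#' @return An \code{ExpressionMatrix} of residuals at the input's stage.
#' @export
residualize_on_age <- function(m, ages) {
  assert_stage(m, c("log2", "batch_adjusted"), "residualize_on_age")
  if (length(ages) != ncol(m$values)) stop("'ages' must match sample count")
  if (length(unique(ages)) < 2L) stop("singular design: all ages identical")
  fit <- stats::lm.fit(cbind(1, ages), t(m$values))
  out <- t(fit$residuals)
  dimnames(out) <- dimnames(m$values)
  expression_matrix(out, m$stage)
}

#' Detect skin-youthfulness genes
#'
#' Compares SY with non-SY subjects on age-residualized expression: the age
#' trend is removed by \code{\link{residualize_on_age}} (by default fitted on
#' the SY union non-SY samples; set \code{residualize_on = "all"} to fit the
#' age regression over every sample first), then each gene is regressed on
#' the binary SY indicator and tested with moderated t-statistics. Genes are
#' reported at unadjusted p below \code{p_cut} (the SY contrast is screened
#' on raw p; adjusted p is still returned in the table).
#'
#' @param m preprocessed \code{ExpressionMatrix}.
#' @param ages chronological ages, one per sample of \code{m}.
#' @param classes per-sample class labels; samples labelled \code{"SY"} and
#'   \code{"non-SY"} form the comparison.
#' @param p_cut unadjusted p threshold (default 0.01).
#' @param residualize_on \code{"union"} (default) or \code{"all"}.
#' @return A list: \code{up}, \code{down}, \code{table} (sorted by p).
#' @export
detect_sy_genes <- function(m, ages, classes, p_cut = 0.01,
                            residualize_on = c("union", "all")) {
  residualize_on <- match.arg(residualize_on)
  assert_stage(m, c("log2", "batch_adjusted"), "detect_sy_genes")
  if (length(classes) != ncol(m$values) || length(ages) != ncol(m$values)) {
    stop("'ages' and 'classes' must have one entry per sample")
  }
  sel <- classes %in% c("SY", "non-SY")
  is_sy <- classes[sel] == "SY"
  if (sum(is_sy) < 2L || sum(!is_sy) < 2L) {
    stop("insufficient group: need >= 2 SY and >= 2 non-SY samples")
  }
  resid_m <- if (residualize_on == "all") {
    r <- residualize_on_age(m, ages)
    expression_matrix(r$values[, sel, drop = FALSE], r$stage)
  } else {
    sub <- expression_matrix(m$values[, sel, drop = FALSE], m$stage)
    residualize_on_age(sub, ages[sel])
  }
  fits <- fit_gene_models(resid_m, as.numeric(is_sy))
  res <- moderated_test(fits, estimate_prior(fits))
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p), ]
  hit <- !is.na(res$p) & res$p < p_cut
  list(up = res$gene_id[hit & res$direction == "up"],
       down = res$gene_id[hit & res$direction == "down"],
       table = res)
}

#' Write a differential-expression result table as TSV
#'
#' @param result list from \code{\link{detect_age_genes}} or
#'   \code{\link{detect_sy_genes}}.
#' @param path output path.
#' @export
write_de_tsv <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
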