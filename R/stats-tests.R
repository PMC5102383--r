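#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, two-sided.
#'
#' @param group1,group2 numeric vectors, each with at least 2 values and
#'   positive variance.
#' @return A list of class \code{"sy_test"}: \code{statistic}, \code{p},
#'   \code{df}, \code{method}.
#' @export
welch_t <- function(group1, group2) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  if (length(group1) < 2L || length(group2) < 2L ||
      stats::var(group1) <= 0 || stats::var(group2) <= 0) {
    stop("insufficient data: each group needs >= 2 values with positive variance")
  }
  ht <- stats::t.test(group1, group2, var.equal = FALSE)
  sy_test(unname(ht$statistic), ht$p.value, unname(ht$parameter),
          "Welch two-sample t-test")
}

sy_test <- function(statistic, p, df = NA_real_, method = "") {
  structure(list(statistic = statistic, p = p, df = df, method = method),
            class = "sy_test")
}

#' @export
print.sy_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      if (!is.na(x$df)) paste(" df =", format(x$df)),
      " p =", format(x$p), "\n")
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: with margins fixed, the
#' p-value sums hypergeometric probabilities over all tables whose point
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative slack against floating-point equality).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome yes/no), or a vector (a, b, c, d) filled by row.
#' @return A \code{"sy_test"} with the conditional odds-ratio estimate as the
#'   statistic.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("invalid table: counts must be non-negative integers")
  }
  if (sum(tab) == 0) stop("invalid table: all counts are zero")
  ht <- stats::fisher.test(tab)
  sy_test(unname(ht$estimate), ht$p.value, method = "Fisher's exact test")
}

# Exact null distribution of the (doubled, integer) rank sum of group 1:
# dynamic programming over which of the n observations fall in group 1.
# ranks2 = 2 * mid-ranks (integers even under ties), n1 = size of group 1.
# Returns P(W2 = s) for s = 0..sum(ranks2) as a numeric vector (index s + 1).
ranksum_null_dp <- function(ranks2, n1) {
  n <- length(ranks2)
  smax <- sum(ranks2)
  ways <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  ways[1L, 1L] <- 1
  for (r in ranks2) {
    top <- min(n1, n) # rows that can still grow
    for (c in rev(seq_len(top))) {
      shifted <- c(rep(0, r), ways[c, seq_len(smax + 1L - r)])
      ways[c + 1L, ] <- ways[c + 1L, ] + shifted
    }
  }
  ways[n1 + 1L, ] / choose(n, n1)
}

#' Wilcoxon rank-sum test
#'
#' For small samples (total below \code{exact_below_n}) the exact permutation
#' null of the rank sum is computed by dynamic programming over all
#' assignments of the pooled observations to the two groups, using mid-ranks
#' for ties; the two-sided p is twice the smaller tail, capped at 1. For
#' larger samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param group1,group2 numeric vectors, each non-empty.
#' @param exact_below_n use the exact path when n1 + n2 is below this
#'   (default 25).
#' @return A \code{"sy_test"} whose statistic is the rank sum of group 1.
#' @export
wilcoxon_rank_sum <- function(group1, group2, exact_below_n = 25L) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  n1 <- length(group1)
  n2 <- length(group2)
  if (n1 < 1L || n2 < 1L) stop("insufficient data: both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(group1, group2))          # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  if (n < exact_below_n) {
    r2 <- as.integer(round(2 * r))
    pmf <- ranksum_null_dp(r2, n1)
    w2 <- as.integer(round(2 * W))
    lower <- sum(pmf[seq_len(w2 + 1L)])
    upper <- sum(pmf[(w2 + 1L):length(pmf)])
    p <- min(1, 2 * min(lower, upper))
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  sy_test(W, p, method = method)
}

#' Pearson correlation with t-based significance
#'
#' @param x,y numeric vectors of equal length n >= 3, both non-constant.
#' @return A \code{"sy_test"} with the correlation coefficient r as the
#'   statistic and a two-sided p from t = r sqrt((n-2)/(1-r^2)) on n-2 df.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("insufficient data: need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  out <- sy_test(unname(ht$estimate), ht$p.value, unname(ht$parameter),
                 "Pearson correlation")
  out
}

#' Delta-Ct normalisation for RT-qPCR
#'
#' Averages technical replicates per sample, then subtracts the reference
#' (housekeeping) Ct from the target Ct: higher delta-Ct means lower target
#' expression relative to the control gene.
#'
#' @param target_ct,reference_ct numeric vectors (one Ct per sample) or
#'   matrices with samples in rows and replicate measurements in columns;
#'   sample counts must match.
#' @return Numeric vector of per-sample delta-Ct values.
#' @export
qpcr_delta_ct <- function(target_ct, reference_ct) {
  avg <- function(x) if (is.matrix(x)) rowMeans(x) else x
  tg <- avg(target_ct)
  rf <- avg(reference_ct)
  if (length(tg) != length(rf)) {
    stop("pairing error: target and reference must cover the same samples")
  }
  tg - rf
}

#' Covariate balance table between SY and non-SY groups
#'
#' Builds a demographics-style balance table: numeric covariates are
#' summarised as mean (sd) and compared by Welch's t-test; binary covariates
#' as count (percent) and compared by Fisher's exact test.
#'
#' @param cohort data frame with \code{subject_id} and covariate columns.
#' @param assignments phenotype data frame with \code{subject_id} and
#'   \code{class} (from \code{\link{phenotype_cohort}}).
#' @param numeric_covariates,binary_covariates column names to compare.
#' @return Data frame: parameter, sy_summary, nonsy_summary, test, p.
#' @export
covariate_balance <- function(cohort, assignments,
                              numeric_covariates = c("age", "bmi", "uv_score"),
                              binary_covariates = c("smoker", "skin_cancer")) {
  cls <- assignments$class[match(cohort$subject_id, assignments$subject_id)]
  sy <- cohort[cls %in% "SY", , drop = FALSE]
  nonsy <- cohort[cls %in% "non-SY", , drop = FALSE]
  if (nrow(sy) == 0L || nrow(nonsy) == 0L) {
    stop("cannot compare covariates: an SY or non-SY group is empty")
  }
  rows <- list()
  for (v in numeric_covariates) {
    tt <- welch_t(sy[[v]], nonsy[[v]])
    rows[[v]] <- data.frame(
      parameter = v,
      sy_summary = sprintf("%.1f (%.1f)", mean(sy[[v]]), stats::sd(sy[[v]])),
      nonsy_summary = sprintf("%.1f (%.1f)", mean(nonsy[[v]]), stats::sd(nonsy[[v]])),
      test = "Welch t", p = tt$p, stringsAsFactors = FALSE)
  }
  for (v in binary_covariates) {
    tab <- matrix(c(sum(sy[[v]] == 1), sum(sy[[v]] == 0),
                    sum(nonsy[[v]] == 1), sum(nonsy[[v]] == 0)),
                  2, 2, byrow = TRUE)
    ft <- fisher_exact(tab)
    rows[[v]] <- data.frame(
      parameter = v,
      sy_summary = sprintf("%d (%.0f%%)", sum(sy[[v]] == 1),
                           100 * mean(sy[[v]] == 1)),
      nonsy_summary = sprintf("%d (%.0f%%)", sum(nonsy[[v]] == 1),
                              100 * mean(nonsy[[v]] == 1)),
      test = "Fisher exact", p = ft$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
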