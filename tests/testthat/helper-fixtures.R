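# Shared fixtures and independent oracles used across test files.

toy_matrix <- function(values, stage = "raw", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  expression_matrix(m, stage)
}

# Closed-form simple linear regression: the normal-equations oracle.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  list(intercept = intercept, slope = slope,
       residuals = y - intercept - slope * x)
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the point probabilities not exceeding the observed one.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  # hypergeometric pmf from binomial coefficients directly
  pk <- choose(r1, ks) * choose(N - r1, c1 - ks) / choose(N, c1)
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating every split of the pooled sample.
wilcoxon_enum_oracle <- function(g1, g2) {
  n1 <- length(g1)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  sums <- combn(length(pooled), n1, function(idx) sum(r[idx]))
  lower <- mean(sums <= W + 1e-9)
  upper <- mean(sums >= W - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Upper-tail hypergeometric by direct summation of binomial-coefficient mass:
# P(overlap >= k) for a set of size K in a universe of size N with n changed.
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up applied literally to a p-value vector.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Small simulated study used by several files.
small_study <- function(seed = 1, ...) {
  simulate_study(sim_config(n_subjects = 40, n_genes = 300, n_age_genes = 20,
                            n_sy_genes = 10, seed = seed, ...))
}
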