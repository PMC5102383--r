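#' Normalise counts to a fixed sequencing depth
#'
#' Rescales every sample (column) so that its total count equals
#' \code{target} mapped reads. The default target of 10 million reads is the
#' conventional depth unit for 3'-end sequencing, where each transcript
#' contributes one counting unit regardless of length, so no length
#' correction is applied.
#'
#' @param m an \code{ExpressionMatrix} at stage \code{"raw"}.
#' @param target total count each sample is scaled to (default 1e7).
#' @return An \code{ExpressionMatrix} at stage \code{"normalized"} whose
#'   column sums all equal \code{target}.
#' @export
normalize_counts <- function(m, target = 1e7) {
  assert_stage(m, "raw", "normalize_counts")
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  totals <- colSums(m$values)
  if (any(totals <= 0)) {
    bad <- colnames(m$values)[totals <= 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  scaled <- sweep(m$values, 2L, target / totals, "*")
  expression_matrix(scaled, "normalized")
}

#' Keep genes expressed above a mean threshold
#'
#' Retains genes whose mean normalised expression is strictly greater than
#' \code{min_mean} (default 2 on the counts-per-10M scale), dropping genes too
#' lowly expressed to analyse. Gene order is preserved.
#'
#' @param m an \code{ExpressionMatrix} at stage \code{"normalized"}.
#' @param min_mean threshold on the per-gene mean (strict inequality).
#' @return The filtered \code{ExpressionMatrix}, still at stage
#'   \code{"normalized"}.
#' @export
filter_expressed <- function(m, min_mean = 2.0) {
  assert_stage(m, "normalized", "filter_expressed")
  keep <- rowMeans(m$values) > min_mean
  if (!any(keep)) {
    warning("no genes pass the expression filter (mean > ", min_mean, ")")
  }
  expression_matrix(m$values[keep, , drop = FALSE], "normalized")
}

#' Log2-transform normalised expression values
#'
#' Applies \code{log2(x + pseudocount)}. The pseudocount (default 1) keeps
#' zero counts finite; on the counts-per-10M scale a unit pseudocount is small
#' relative to expressed genes.
#'
#' @param m an \code{ExpressionMatrix} at stage \code{"normalized"}.
#' @param pseudocount value added before taking logs; must be > 0.
#' @return An \code{ExpressionMatrix} at stage \code{"log2"}.
#' @export
log2_transform <- function(m, pseudocount = 1.0) {
  assert_stage(m, "normalized", "log2_transform")
  stopifnot(pseudocount > 0)
  if (any(m$values < 0)) stop("negative values cannot be log2-transformed")
  expression_matrix(log2(m$values + pseudocount), "log2")
}

#' Remove batch effects by parametric empirical-Bayes adjustment
#'
#' Location/scale batch correction on the log2 matrix. Per gene the grand mean
#' and pooled variance are estimated and the data standardised; per batch and
#' gene a location shift (gamma) and scale factor (delta^2) are estimated and
#' shrunk towards per-batch priors - normal for locations, inverse-gamma for
#' scales - whose hyperparameters are fitted across genes by the method of
#' moments. The shrunken batch effects are solved by fixed-point iteration
#' (the location and scale estimates depend on each other), then removed, and
#' the grand mean and pooled variance restored. After adjustment each gene is
#' recentred so its grand mean is preserved exactly.
#'
#' With a single batch the input is returned unchanged (tagged
#' \code{batch_adjusted}): there is nothing to remove.
#'
#' @param m an \code{ExpressionMatrix} at stage \code{"log2"}.
#' @param batches vector of batch labels, one per sample.
#' @param tol convergence tolerance of the fixed-point iteration.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return A list with elements \code{matrix} (an \code{ExpressionMatrix} at
#'   stage \code{"batch_adjusted"}) and \code{model} (a \code{BatchModel} with
#'   the shrunken per-batch location shifts, scale factors and prior
#'   hyperparameters).
#' @export
batch_adjust <- function(m, batches, tol = 1e-4, max_iter = 500L) {
  assert_stage(m, "log2", "batch_adjust")
  Y <- m$values
  if (length(batches) != ncol(Y)) {
    stop("'batches' must have one label per sample")
  }
  batches <- factor(batches)
  nb <- table(batches)
  if (nlevels(batches) == 1L) {
    out <- expression_matrix(Y, "batch_adjusted")
    model <- structure(list(batch_levels = levels(batches), gamma_star = NULL,
                            delta2_star = NULL, priors = NULL),
                       class = "BatchModel")
    return(list(matrix = out, model = model))
  }
  if (any(nb < 2L)) {
    stop("degenerate batch with < 2 samples: ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  }

  n <- ncol(Y)
  G <- nrow(Y)
  levs <- levels(batches)
  B <- length(levs)

  # standardisation: grand mean = sample-size weighted batch means; pooled
  # variance = variance about the grand mean
  batch_means <- vapply(levs, function(b)
    rowMeans(Y[, batches == b, drop = FALSE]), numeric(G))
  w <- as.numeric(nb[levs]) / n
  grand <- drop(batch_means %*% w)
  # variance pooled over samples about their own batch mean, so scale is not
  # inflated by the batch shifts themselves
  pooled_var <- rowSums((Y - batch_means[, as.integer(batches), drop = FALSE])^2) / n
  if (any(pooled_var <= 0)) {
    stop("gene(s) with zero pooled variance cannot be standardised: ",
         paste(utils::head(rownames(Y)[pooled_var <= 0], 5), collapse = ", "))
  }
  Z <- (Y - grand) / sqrt(pooled_var)

  gamma_star <- matrix(NA_real_, G, B, dimnames = list(rownames(Y), levs))
  delta2_star <- gamma_star
  priors <- vector("list", B)
  names(priors) <- levs

  for (b in seq_along(levs)) {
    idx <- batches == levs[b]
    nj <- sum(idx)
    Zb <- Z[, idx, drop = FALSE]
    g_hat <- rowMeans(Zb)                       # per-gene batch location
    d2_hat <- rowSums((Zb - g_hat)^2) / (nj - 1)  # per-gene batch scale

    # method-of-moments hyperparameters across genes
    gbar <- mean(g_hat)
    tau2 <- stats::var(g_hat)
    m_d <- mean(d2_hat)
    v_d <- stats::var(d2_hat)
    degenerate_scale <- !is.finite(v_d) || v_d <= m_d^2 * 1e-12
    lambda <- if (degenerate_scale) Inf else (m_d^2 + 2 * v_d) / v_d  # IG shape
    theta <- if (degenerate_scale) Inf else (m_d^3 + m_d * v_d) / v_d # IG rate

    # fixed point: gamma* shrinks towards gbar with weight depending on
    # delta2*; delta2* is the posterior scale given gamma*
    if (degenerate_scale) {
      # all genes share one scale: the inverse-gamma prior collapses and the
      # posterior scale is that common value; the location update is closed
      # form (tau2 = 0 likewise collapses the location prior onto gbar)
      d2_new <- rep(m_d, G)
      g_new <- if (tau2 <= 1e-300) rep(gbar, G) else
        (tau2 * nj * g_hat + d2_new * gbar) / (tau2 * nj + d2_new)
    } else {
      g_new <- g_hat
      d2_new <- d2_hat
      change <- Inf
      iter <- 0L
      sZ2 <- rowSums(Zb^2)
      while (change > tol) {
        iter <- iter + 1L
        if (iter > max_iter) {
          stop(sprintf("batch-effect shrinkage did not converge after %d iterations (max residual %.3g)",
                       max_iter, change))
        }
        g_old <- g_new
        d2_old <- d2_new
        g_new <- (tau2 * nj * g_hat + d2_new * gbar) / (tau2 * nj + d2_new)
        sse <- sZ2 - 2 * g_new * nj * g_hat + nj * g_new^2
        d2_new <- (theta + 0.5 * sse) / (nj / 2 + lambda - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d2_new - d2_old) / pmax(abs(d2_old), 1e-12))
      }
    }
    gamma_star[, b] <- g_new
    delta2_star[, b] <- d2_new
    priors[[b]] <- list(gamma_bar = gbar, tau2 = tau2,
                        lambda = lambda, theta = theta)
  }

  Zadj <- Z
  for (b in seq_along(levs)) {
    idx <- batches == levs[b]
    Zadj[, idx] <- (Z[, idx, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  Yadj <- Zadj * sqrt(pooled_var) + grand
  # restore the grand mean exactly (shrinkage leaves a small residual offset)
  Yadj <- Yadj - (drop(vapply(levs, function(b)
    rowMeans(Yadj[, batches == b, drop = FALSE]), numeric(G)) %*% w) - grand)

  model <- structure(list(batch_levels = levs, gamma_star = gamma_star,
                          delta2_star = delta2_star, priors = priors),
                     class = "BatchModel")
  list(matrix = expression_matrix(Yadj, "batch_adjusted"), model = model)
}

#' Run the full count-preprocessing chain
#'
#' Convenience wrapper: depth normalisation, expressed-gene filter, log2
#' transform, and (when batch labels are given) empirical-Bayes batch
#' adjustment, in that order.
#'
#' @inheritParams normalize_counts
#' @inheritParams filter_expressed
#' @inheritParams log2_transform
#' @param batches optional batch labels; if \code{NULL} the batch step is
#'   skipped and the matrix is returned at stage \code{"log2"}.
#' @return An \code{ExpressionMatrix} at the final stage reached.
#' @export
preprocess_counts <- function(m, batches = NULL, target = 1e7, min_mean = 2.0,
                              pseudocount = 1.0) {
  out <- log2_transform(filter_expressed(normalize_counts(m, target), min_mean),
                        pseudocount)
  if (!is.null(batches)) out <- batch_adjust(out, batches)$matrix
  out
}
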