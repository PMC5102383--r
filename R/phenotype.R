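#' Aggregate rater scores into a skin age score (SAS)
#'
#' The skin age score of a subject is the median of the blinded raters'
#' scores; with an even number of raters, the midpoint of the two central
#' values.
#'
#' @param rater_scores numeric vector of per-rater scores in years.
#' @return The median score in years.
#' @export
aggregate_sas <- function(rater_scores) {
  rater_scores <- rater_scores[!is.na(rater_scores)]
  if (length(rater_scores) == 0L) stop("missing scores: no finite rater scores")
  if (any(!is.finite(rater_scores))) stop("missing scores: non-finite rater score")
  stats::median(rater_scores)
}

#' Delta: chronological age minus skin age score
#'
#' Positive delta means the skin looks younger than the calendar age.
#'
#' @param ca chronological age in years.
#' @param sas skin age score in years (must be positive).
#' @return \code{ca - sas} in years.
#' @examples
#' compute_delta(65, 80)  # skin looks 15 years older than the calendar age
#' compute_delta(60, 59)
#' @export
compute_delta <- function(ca, sas) {
  if (!all(is.finite(ca)) || !all(is.finite(sas))) {
    stop("invalid input: age and skin age score must be finite")
  }
  if (any(sas <= 0)) stop("invalid input: skin age score must be positive")
  ca - sas
}

#' Regress delta on chronological age
#'
#' Because the spread of delta grows with chronological age, delta itself is a
#' biased youthfulness measure. Fitting delta ~ age by ordinary least squares
#' over all subjects and keeping the residual (r_delta) removes the
#' age trend; r_delta is the quantitative youthfulness phenotype.
#'
#' @param delta numeric vector of deltas (years).
#' @param age numeric vector of chronological ages (years), same length.
#' @return A list of class \code{"delta_regression"}: \code{intercept},
#'   \code{slope}, \code{residuals} (named like \code{delta} if it has names),
#'   \code{n_fit}.
#' @export
fit_delta_regression <- function(delta, age) {
  stopifnot(length(delta) == length(age))
  ok <- is.finite(delta) & is.finite(age)
  if (sum(ok) < 3L) stop("need at least 3 subjects with finite delta and age")
  if (length(unique(age[ok])) < 2L) {
    stop("singular design: all ages identical")
  }
  fit <- stats::lm.fit(cbind(1, age[ok]), delta[ok])
  res <- rep(NA_real_, length(delta))
  res[ok] <- fit$residuals
  names(res) <- names(delta)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 residuals = res, n_fit = sum(ok)),
            class = "delta_regression")
}

#' Compute phenotype assignments for a cohort
#'
#' For each subject: SAS (median rater score), delta = age - SAS, and r_delta
#' (residual from the delta-on-age regression fitted over all subjects), then
#' class labels via \code{\link{classify_subjects}}.
#'
#' @param cohort data frame with columns \code{subject_id}, \code{age}, and
#'   rater-score columns matching \code{rater_cols}.
#' @param rater_cols names (or a regular expression if \code{regex = TRUE}) of
#'   the rater-score columns; default all columns starting with "rater".
#' @param ... passed to \code{\link{classify_subjects}}.
#' @return A data frame (subject_id, age, sas, delta, r_delta, class) with the
#'   regression fit attached as attribute \code{"fit"}.
#' @export
phenotype_cohort <- function(cohort, rater_cols = grep("^rater", names(cohort),
                                                       value = TRUE), ...) {
  if (length(rater_cols) == 0L) stop("no rater-score columns found")
  sas <- apply(cohort[, rater_cols, drop = FALSE], 1L, aggregate_sas)
  delta <- compute_delta(cohort$age, sas)
  fit <- fit_delta_regression(delta, cohort$age)
  out <- data.frame(subject_id = cohort$subject_id, age = cohort$age,
                    sas = sas, delta = delta,
                    r_delta = unname(fit$residuals),
                    stringsAsFactors = FALSE)
  out <- classify_subjects(out, ...)
  attr(out, "fit") <- fit
  out
}

#' Classify subjects as young / SY / non-SY / mid-age / unclassified
#'
#' Subjects younger than \code{young_age_max} are the "young" positive-control
#' group. Among subjects aged \code{sy_age_min} or older (the eligible
#' stratum), those with r_delta in the top \code{sy_top_fraction} (count =
#' ceiling of the fraction times the stratum size; ties broken by subject id)
#' are skin-youthful (SY); those at or below the stratum's
#' \code{nonsy_lower_fraction} quantile of r_delta are non-SY; remaining
#' eligible subjects are unclassified. Subjects between the two age gates are
#' labelled mid-age.
#'
#' @param assignments data frame with \code{subject_id}, \code{age},
#'   \code{r_delta}.
#' @param sy_top_fraction fraction of the eligible stratum labelled SY
#'   (default 0.10).
#' @param nonsy_lower_fraction quantile bound for non-SY (default 0.50).
#' @param sy_age_min minimum age for SY/non-SY eligibility (default 50,
#'   inclusive).
#' @param young_age_max exclusive upper age of the young group (default 30).
#' @param lower_within_stratum if \code{TRUE} (default) the non-SY quantile is
#'   computed within the eligible stratum; if \code{FALSE}, over all subjects.
#' @return \code{assignments} with a \code{class} factor column added.
#' @export
classify_subjects <- function(assignments, sy_top_fraction = 0.10,
                              nonsy_lower_fraction = 0.50, sy_age_min = 50,
                              young_age_max = 30,
                              lower_within_stratum = TRUE) {
  stopifnot(all(c("subject_id", "age", "r_delta") %in% names(assignments)))
  if (any(!is.finite(assignments$r_delta))) {
    stop("r_delta must be populated for every subject")
  }
  age <- assignments$age
  r <- assignments$r_delta
  cls <- rep("mid-age", nrow(assignments))
  cls[age < young_age_max] <- "young"

  eligible <- which(age >= sy_age_min)
  if (length(eligible) == 0L) {
    warning("no subjects aged >= ", sy_age_min, "; SY/non-SY sets are empty")
  } else {
    cls[eligible] <- "unclassified"
    m <- length(eligible)
    n_sy <- ceiling(sy_top_fraction * m)
    ord <- eligible[order(-r[eligible], assignments$subject_id[eligible])]
    sy <- ord[seq_len(min(n_sy, m))]
    pool <- if (lower_within_stratum) r[eligible] else r
    cut <- stats::quantile(pool, nonsy_lower_fraction, type = 7, names = FALSE)
    nonsy <- setdiff(eligible[r[eligible] <= cut], sy)
    cls[sy] <- "SY"
    cls[nonsy] <- "non-SY"
  }
  assignments$class <- factor(cls, levels = c("young", "mid-age", "SY",
                                              "non-SY", "unclassified"))
  assignments
}

#' Write phenotype assignments as CSV
#'
#' @param assignments data frame from \code{\link{phenotype_cohort}}.
#' @param path output CSV path.
#' @export
write_phenotype_csv <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
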