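#' Configuration for the synthetic cohort and count-matrix generator
#'
#' Collects every knob of the simulator with defaults chosen to mirror the
#' structure of a dermatology ageing cohort profiled by 3'-end RNA-seq:
#' ~122 healthy volunteers aged 18-89 scored by four blinded raters, a delta
#' (chronological age minus skin age score) whose spread grows with age, an
#' overdispersed count matrix with injected age- and youthfulness-associated
#' genes, multiplicative library-size variation and additive log-scale batch
#' shifts.
#'
#' @param n_subjects number of subjects (default 122).
#' @param age_range two ages (years); subjects drawn uniformly over the
#'   integer years in this range (default 18-89).
#' @param n_raters number of independent skin-age raters (default 4).
#' @param rater_sd per-rater scoring noise sd in years (default 2).
#' @param delta_slope mean growth of delta per year of age (default 0.1).
#' @param delta_noise_base,delta_noise_age heteroscedastic delta noise:
#'   sd(age) = base + age * coef years, so older subjects show a wider spread
#'   of delta (defaults 2 and 0.1: sd ~3.8y at 18, ~10.9y at 89).
#' @param n_genes number of genes (default 5000).
#' @param n_age_genes,n_sy_genes counts of injected age- and SY-effect genes
#'   (defaults 100 and 50), injected as balanced up/down pairs so the
#'   injected programme conserves expected per-sample totals.
#' @param age_effect_log2_per_year log2 expression change per year of age for
#'   age genes (default 0.03, about a two-fold change per 23 years).
#' @param sy_effect_log2 log2 shift in true-SY subjects for SY genes
#'   (default 2).
#' @param nb_dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.1, a biological CV of ~32\%).
#' @param n_batches number of sequencing batches (default 2).
#' @param batch_shift_log2 additive log2 shift applied to every gene in each
#'   batch after the first (batch b gets (b-1) times this; default 1).
#' @param libsize_log_mean,libsize_log_sd log-normal library-size factor
#'   parameters (defaults 3.2 and 0.4: per-sample totals near 10 million
#'   reads at the default gene count, with a ~3-fold depth range, so
#'   expressed genes sit well clear of the discrete low-count regime).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 abundance (defaults 5 and 2).
#' @param sy_top_fraction fraction of eligible (age >= 50) subjects recorded
#'   as true-SY ground truth (default 0.10).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects = 122L, age_range = c(18, 89),
                       n_raters = 4L, rater_sd = 2,
                       delta_slope = 0.1, delta_noise_base = 2,
                       delta_noise_age = 0.1,
                       n_genes = 5000L, n_age_genes = 100L, n_sy_genes = 50L,
                       age_effect_log2_per_year = 0.03, sy_effect_log2 = 2,
                       nb_dispersion = 0.1, n_batches = 2L,
                       batch_shift_log2 = 1,
                       libsize_log_mean = 3.2, libsize_log_sd = 0.4,
                       baseline_log2_mean = 5, baseline_log2_sd = 2,
                       sy_top_fraction = 0.10, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
              n_raters = as.integer(n_raters), rater_sd = rater_sd,
              delta_slope = delta_slope, delta_noise_base = delta_noise_base,
              delta_noise_age = delta_noise_age,
              n_genes = as.integer(n_genes),
              n_age_genes = as.integer(n_age_genes),
              n_sy_genes = as.integer(n_sy_genes),
              age_effect_log2_per_year = age_effect_log2_per_year,
              sy_effect_log2 = sy_effect_log2,
              nb_dispersion = nb_dispersion,
              n_batches = as.integer(n_batches),
              batch_shift_log2 = batch_shift_log2,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              sy_top_fraction = sy_top_fraction, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("invalid config: n_subjects must be positive")
  if (cfg$n_raters < 1L) stop("invalid config: n_raters must be positive")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    stop("invalid config: age_range must be an increasing pair")
  }
  if (cfg$n_age_genes + cfg$n_sy_genes > cfg$n_genes) {
    stop("invalid config: n_age_genes + n_sy_genes exceeds n_genes")
  }
  sds <- c(cfg$rater_sd, cfg$delta_noise_base, cfg$delta_noise_age,
           cfg$libsize_log_sd, cfg$baseline_log2_sd)
  if (any(sds < 0)) stop("invalid config: all sds must be >= 0")
  if (cfg$nb_dispersion < 0) stop("invalid config: nb_dispersion must be >= 0")
  if (cfg$n_batches < 1L) stop("invalid config: n_batches must be positive")
  invisible(cfg)
}

#' Simulate a scored cohort with latent skin youthfulness
#'
#' Draws chronological ages uniformly over the configured range and gives each
#' subject a latent youthfulness u ~ N(0, 1). The true skin age score is
#' \code{age - delta_slope * age - u * (delta_noise_base + delta_noise_age *
#' age)}: the latent trait enters scaled by the age-dependent noise sd, so the
#' spread of delta grows with age while subjects with large u keep the
#' youngest-looking skin. Each rater reports the true score plus N(0,
#' rater_sd) noise, rounded to whole years and clamped to [18, 100]
#' (clinicians rate in whole years). Covariates (BMI, smoking, prior skin
#' cancer, lifetime UV score) are drawn independently of u, so group balance
#' tests are null-true by construction. Subjects aged >= 50 with the largest
#' u (top \code{sy_top_fraction}) are recorded as ground-truth SY.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{cohort} (data frame: subject_id, age,
#'   one column per rater score, batch, bmi, smoker, skin_cancer, uv_score)
#'   and \code{truth} (list: true_r_delta = the latent u, true_sy_subjects,
#'   and empty gene slots filled in by \code{\link{generate_counts}}).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  u <- stats::rnorm(n)
  noise_sd <- config$delta_noise_base + config$delta_noise_age * age
  true_sas <- age - config$delta_slope * age - u * noise_sd
  scores <- matrix(NA_real_, n, config$n_raters)
  for (r in seq_len(config$n_raters)) {
    raw <- true_sas + stats::rnorm(n, sd = config$rater_sd)
    scores[, r] <- pmin(pmax(round(raw), 18), 100)
  }
  colnames(scores) <- paste0("rater", seq_len(config$n_raters))

  subject_id <- sprintf("S%03d", seq_len(n))
  cohort <- data.frame(
    subject_id = subject_id,
    age = age,
    scores,
    batch = paste0("B", rep_len(seq_len(config$n_batches), n)),
    bmi = round(stats::rnorm(n, 25, 4), 1),
    smoker = stats::rbinom(n, 1L, 0.3),
    skin_cancer = stats::rbinom(n, 1L, 0.25),
    uv_score = round(stats::rlnorm(n, log(35), 0.6), 1),
    stringsAsFactors = FALSE
  )

  eligible <- which(age >= 50)
  n_sy <- if (length(eligible)) ceiling(config$sy_top_fraction * length(eligible)) else 0L
  sy_idx <- eligible[order(-u[eligible], subject_id[eligible])][seq_len(n_sy)]
  truth <- list(true_r_delta = stats::setNames(u, subject_id),
                true_sy_subjects = sort(subject_id[sy_idx]),
                age_genes = NULL, sy_genes = NULL)
  list(cohort = cohort, truth = truth)
}

#' Simulate an overdispersed 3'-seq count matrix over a cohort
#'
#' Each gene g in sample j has log2 mean
#' \code{baseline_g + age_effect * age_j * sign_g [age gene] + sy_effect *
#' sign_g [SY gene, true-SY subject] + (batch_j - 1) * batch_shift_log2}.
#' Counts are negative binomial with that mean multiplied by a log-normal
#' library-size factor L_j. Effect genes come in balanced up/down pairs that
#' conserve expected totals, so per-sample totals divided by L_j are constant
#' in expectation and depth normalisation carries no composition bias. The
#' first \code{n_age_genes} genes carry age effects and the next
#' \code{n_sy_genes} carry SY effects (ids and signs are returned in the
#' ground truth).
#'
#' @param cohort cohort data frame from \code{\link{generate_cohort}}.
#' @param truth ground-truth list from \code{\link{generate_cohort}}; returned
#'   augmented with the injected gene ids and signs.
#' @param config the same \code{\link{sim_config}}.
#' @return A list with elements \code{matrix} (an \code{ExpressionMatrix} at
#'   stage \code{"raw"}), \code{truth} (augmented), and \code{libsize}
#'   (named vector of L_j).
#' @export
generate_counts <- function(cohort, truth, config) {
  validate_sim_config(config)
  if (nrow(cohort) == 0L) stop("cohort is empty")
  set.seed(config$seed + 1000003L)  # independent stream from the cohort draw
  G <- config$n_genes
  n <- nrow(cohort)
  gene_id <- sprintf("G%05d", seq_len(G))

  baseline <- stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
  age_idx <- seq_len(config$n_age_genes)
  sy_idx <- config$n_age_genes + seq_len(config$n_sy_genes)
  # balanced up/down pairs: expression gained by the up member of a pair is
  # lost by its down member, so injected effects conserve expected per-sample
  # totals and do not leak composition bias into depth normalisation.
  # Age pairs share a baseline (linear drift cancels); SY pairs offset the
  # down member's baseline by the effect size (exact cancellation for a
  # binary group shift).
  paired <- function(n, offset) {
    sign <- rep_len(c(1, -1), n)
    base <- numeric(n)
    if (n > 0) {
      pair_of <- (seq_len(n) + 1L) %/% 2L
      b <- stats::rnorm(max(pair_of), config$baseline_log2_mean,
                        config$baseline_log2_sd)
      base <- b[pair_of] + ifelse(sign < 0, offset, 0)
    }
    list(sign = sign, base = base)
  }
  age_pairs <- paired(config$n_age_genes, 0)
  sy_pairs <- paired(config$n_sy_genes, config$sy_effect_log2)
  age_sign <- age_pairs$sign
  sy_sign <- sy_pairs$sign
  baseline[age_idx] <- age_pairs$base
  baseline[sy_idx] <- sy_pairs$base

  log2mu <- matrix(baseline, G, n)
  if (config$n_age_genes > 0) {
    # centre the age covariate so injected genes stay near their baseline
    age_c <- cohort$age - mean(cohort$age)
    log2mu[age_idx, ] <- log2mu[age_idx, ] +
      outer(age_sign * config$age_effect_log2_per_year, age_c)
  }
  if (config$n_sy_genes > 0) {
    is_sy <- as.numeric(cohort$subject_id %in% truth$true_sy_subjects)
    log2mu[sy_idx, ] <- log2mu[sy_idx, ] +
      outer(sy_sign * config$sy_effect_log2, is_sy)
  }
  batch_num <- as.integer(factor(cohort$batch))
  log2mu <- sweep(log2mu, 2L, (batch_num - 1L) * config$batch_shift_log2, "+")

  L <- stats::rlnorm(n, config$libsize_log_mean, config$libsize_log_sd)
  mu <- sweep(2^log2mu, 2L, L, "*")
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(G * n, mu = mu, size = 1 / config$nb_dispersion), G, n)
  } else {
    matrix(stats::rpois(G * n, lambda = mu), G, n)
  }
  dimnames(counts) <- list(gene_id, cohort$subject_id)

  truth$age_genes <- data.frame(gene_id = gene_id[age_idx],
                                sign = age_sign, stringsAsFactors = FALSE)
  truth$sy_genes <- data.frame(gene_id = gene_id[sy_idx],
                               sign = sy_sign, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(counts, "raw"), truth = truth,
       libsize = stats::setNames(L, cohort$subject_id))
}

#' Write a simulated study to disk
#'
#' Writes the cohort metadata as CSV, the raw counts as a gene x sample TSV
#' and the ground truth (true SY subjects, injected genes with signs, latent
#' youthfulness) as CSVs under \code{outdir}.
#'
#' @param sim list with \code{cohort}, \code{matrix}, \code{truth} as produced
#'   by \code{\link{simulate_study}}.
#' @param outdir output directory, created if needed.
#' @return \code{outdir}, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$cohort, file.path(outdir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  write_expression_tsv(sim$matrix, file.path(outdir, "counts.tsv"))
  truth_genes <- rbind(cbind(kind = "age", sim$truth$age_genes),
                       cbind(kind = "sy", sim$truth$sy_genes))
  utils::write.csv(truth_genes, file.path(outdir, "truth_genes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth_subj <- data.frame(subject_id = names(sim$truth$true_r_delta),
                           true_r_delta = unname(sim$truth$true_r_delta),
                           true_sy = names(sim$truth$true_r_delta) %in%
                             sim$truth$true_sy_subjects)
  utils::write.csv(truth_subj, file.path(outdir, "truth_subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(outdir)
}

#' Simulate a full study (cohort plus counts) in one call
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with \code{cohort}, \code{matrix}, \code{truth},
#'   \code{libsize}, \code{config}.
#' @export
simulate_study <- function(config = sim_config()) {
  ch <- generate_cohort(config)
  ct <- generate_counts(ch$cohort, ch$truth, config)
  list(cohort = ch$cohort, matrix = ct$matrix, truth = ct$truth,
       libsize = ct$libsize, config = config)
}
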