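---
title: "Methods: quantitative skin youthfulness and its transcriptomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative skin youthfulness and its transcriptomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinyouth)
```

## The phenotype model

Some people's facial skin looks markedly younger than their chronological age
(CA), and the gap widens with age. The package quantifies this in three steps.

1. **Skin age score (SAS).** Several clinicians, blinded to CA, each assign an
   apparent skin age in whole years; `aggregate_sas()` takes the median
   (midpoint of the central pair for even rater counts), which is robust to a
   single discordant rater.
2. **Delta.** `compute_delta()` returns CA − SAS in years: positive delta
   means younger-looking skin.
3. **Residual of delta (r_delta).** Raw delta is a biased youthfulness
   measure because its spread grows with CA — a delta of +8 is unremarkable
   at 85 but extreme at 50. `fit_delta_regression()` fits delta ~ CA by OLS
   over *all* subjects (the trend is estimated across the whole age span, not
   only the elderly stratum) and keeps the residual. r_delta is the
   quantitative phenotype; residuals sum to zero and are uncorrelated with CA
   by construction.

`classify_subjects()` turns r_delta into groups: subjects younger than 30 are
the "young" positive controls; among subjects aged **50 or older** (we read
the eligibility gate inclusively) the top `ceiling(0.10 * m)` by r_delta are
SY and those at or below the stratum's median r_delta are non-SY. Ties at
either boundary are broken by subject id so classification is deterministic.
Two points were genuinely open and are decided here: the "lower 50%" cut is
computed **within the eligible stratum** (the alternative — the whole-cohort
median — is exposed via `lower_within_stratum = FALSE`), and the top-decile
count uses the ceiling so a stratum of, say, 68 subjects yields 7 SY rather
than 6. Classification is invariant to adding a constant to every r_delta,
and raising one subject's r_delta can only promote them.

## Preprocessing 3'-end RNA-seq counts

3'-seq counts one sequencing unit per transcript, so no gene-length
correction is appropriate. `normalize_counts()` rescales every sample to 10
million mapped reads; `filter_expressed()` keeps genes with mean normalised
expression strictly greater than 2 (the filter is applied on the
counts-per-10M scale, before the log transform); `log2_transform()` applies
log2(x + 1). The unit pseudocount keeps zeros finite and is negligible for
expressed genes on the counts-per-10M scale. Stage tags (`raw` →
`normalized` → `log2` → `batch_adjusted`) are enforced, so running steps out
of order errors instead of silently producing nonsense.

`batch_adjust()` removes batch effects with the parametric empirical-Bayes
location/scale model: per gene, batch means and the variance pooled about
them are estimated and the matrix standardised; per batch, gene-wise
locations get a normal prior and gene-wise scales an inverse-gamma prior,
with hyperparameters moment-matched across genes; the mutually dependent
posterior location and scale are solved by fixed-point iteration (relative
tolerance 1e-4, cap 500 iterations, non-convergence is an error). Two
implementation choices to note:

* When every gene shows the same batch scale the inverse-gamma moments
  degenerate (zero variance of the scale estimates); the posterior then
  collapses to the common scale in closed form rather than dividing by zero.
* After the adjustment each gene is recentred so its grand mean is preserved
  exactly. Shrinkage otherwise leaves a tiny per-gene offset; the recentring
  makes "batch adjustment does not move a gene's overall level" an exact
  invariant. Apart from this per-gene constant, the output matches
  `sva::ComBat` (the test suite checks agreement to 0.02 log2 units on a
  three-batch example).

Because the empirical-Bayes step *shrinks* per-gene batch effects towards
the batch average, it deliberately does not zero out each gene's observed
batch-mean difference when gene scales are heterogeneous — the residual is
sampling noise retained by shrinkage, of order half the batch-mean standard
error, not a failure to remove the shift. A pure location shift is removed
essentially exactly when gene scales are homogeneous, which is how the batch
tests construct their fixtures.

## Differential expression with moderated t-statistics

`fit_gene_models()` fits, per gene, expression ~ intercept + covariate by
OLS, where the covariate is CA (age genes) or the binary SY indicator (SY
genes). With thousands of genes and few samples, gene-wise variance
estimates are noisy; `estimate_prior()` assumes the residual variances are
draws from a scaled inverse chi-square prior with df `d0` and scale `s02`
and estimates both by moment matching on log variances (the trigamma
inversion is Newton's method). The estimator agrees with `limma::squeezeVar`
to numerical precision and recovers `d0` within 20% when variances truly
come from the prior at 5000 genes. `moderated_test()` forms the posterior
variance `(d0*s02 + d*s2)/(d0 + d)` and the moderated t on `d0 + d` df;
`d0 = 0` gives back the ordinary t-test and `d0 = ∞` complete pooling with a
normal reference. Genes that fit exactly (zero residual variance, e.g. a
gene constructed as a linear function of age) are flagged, excluded from
prior estimation and reported untestable rather than given p = 0.

The two contrasts are thresholded differently on purpose: **age genes** use
Benjamini–Hochberg FDR < 0.01 (the age signal is strong and survives
correction), while **SY genes** use unadjusted p < 0.01 — the SY contrast
(12 vs 33 at realistic effect sizes) is screened at raw p, and the adjusted
p is still reported in the output table. Before the SY contrast, expression
is residualized on CA (`residualize_on_age()`), so SY genes are youthfulness
signals over and above chronological ageing. The age regression for
residualization is fitted, by default, on the SY ∪ non-SY samples (the
compared cohort); fitting it over all samples instead is available via
`residualize_on = "all"`. Both contrasts are two-sided.

## Classical tests and covariate balance

Group balance (a demographics table comparing SY vs non-SY on age, BMI,
smoking, prior skin cancer, lifetime UV) uses Welch's t for numeric and
Fisher's exact test for binary covariates. The two-sided Fisher p follows
the probability-mass rule with a 1e-7 relative slack against floating-point
ties — the convention of `fisher.test` — and is verified against brute-force
hypergeometric enumeration for every 2×2 table with N ≤ 30.
`wilcoxon_rank_sum()` computes the exact permutation null (mid-ranks under
ties) via a count dynamic programme when n1 + n2 < 25 and a tie-corrected,
continuity-corrected normal approximation otherwise; the exact path is
verified against full `combn` enumeration. `qpcr_delta_ct()` implements
replicate-averaged ΔCt normalisation for RT-qPCR verification data.

## Gene-set analysis

The published gene-set step used a GUI tool whose internal algorithm is not
documented; the package implements a documented stand-in with the same
user-facing parameters: `call_changed_genes()` thresholds the SY − non-SY
mean difference of age-residualized expression at |Δ| ≥ 0.3 log2 units
(inclusive, for determinism), and `enrich()` tests each set × direction by
the one-sided hypergeometric upper tail within the tested-gene universe,
with BH correction at 0.1 across all set × direction tests. Up and down
directions are tested separately and both reported. `cumulative_set_test()`
reproduces cumulative-plot comparisons: per member gene, group-mean
expression in SY and non-SY, the two ECDFs over genes, and a paired Wilcoxon
signed-rank test on the per-gene differences (the set-level p-value method
was unstated; the signed-rank choice respects the pairing, and a
Kolmogorov–Smirnov alternative is exposed via `method = "ks"`).

## The simulator and what it does (not) show

`sim_config()` / `simulate_study()` emulate the study design: 122 subjects
with integer ages uniform on 18–89, four raters, and a latent youthfulness
trait u ~ N(0,1) entering the true skin age score scaled by the
age-dependent delta noise sd (base 2 + 0.1·age years), so the spread of
delta grows with age and the most youthful elderly subjects are recoverable
ground truth (the generator records the top decile of u among subjects ≥ 50
as true SY). Rater noise is N(0, 2) years, rounded to whole years and
clamped to [18, 100]. Covariates are drawn independently of u, so balance
tests are null-true by construction.

Counts are negative binomial with a shared dispersion of 0.1 (a biological
CV of ~32%, typical for bulk tissue), per-gene baselines log2-normal
(mean 5, sd 2), log-normal library-size factors (log-mean 3.2, log-sd 0.4:
per-sample totals near 10 million reads at the default gene count with a
~3-fold depth range, so expressed genes sit well clear of the discrete
low-count regime), an additive log2 batch shift of 1 between the two
default batches, 100 age genes at 0.03 log2/year (about two-fold per 23
years — a strong ageing gene) and 50 SY genes at 2 log2 units. Age effects
are applied to the age-centred covariate so injected genes stay in the
realistic abundance range.

Effect genes are injected as **balanced up/down pairs that conserve
expected per-sample totals**: the expression an up-regulated pair member
gains, its down-regulated partner loses (SY pairs offset the down member's
baseline by the effect size, which cancels a binary group shift exactly;
age pairs share a baseline, which cancels the linear drift). This matters
at desk scale: with 50 two-log2-unit effects among only 600 genes, sign-
unbalanced injection shifts SY samples' totals by ~20%, and depth
normalisation then tilts *every* null gene — a composition bias that is
negligible at the real study's ratio of changed to measured genes but would
dominate a scaled-down false-discovery measurement. Conserving totals makes
the small simulated universe behave, for calibration purposes, like the
large real one.

The default gene count is 5000 rather than ~17,000 so the full analysis
runs in seconds; the acceptance checks use 2000 genes (age recovery), 600
genes (SY recovery, keeping the expected false-positive count at raw
p < 0.01 commensurate with 50 true positives) and 5000 genes (null
calibration), sizes chosen so each check completes in well under a minute.

What the simulator does *not* emulate: gene–gene correlation (counts are
conditionally independent given the design), gene-specific dispersions,
rater bias or inter-rater correlation, covariate–phenotype confounding, and
any nonlinear age trajectory. Passing recovery tests therefore show that
the pipeline's inference is correct and calibrated under its own modelling
assumptions — not that those assumptions hold in real skin biopsies.

## Numerical conventions

* OLS is solved by QR (`lm.fit`); the delta regression requires ≥ 3 subjects
  and at least two distinct ages, else a singular-design error.
* BH adjustment delegates to `p.adjust(method = "BH")` after validating
  p ∈ (0, 1]; tests pin it to the literal step-up computed by hand.
* Hierarchical clustering uses 1 − Pearson distance and average linkage
  (`hclust`); constant items are an error under the correlation metric.
  The published work's clustering tool defaults are not documented, so this
  choice is ours and is stated, not asserted, as equivalent.
* Heatmap sample order ranks subjects by decreasing r_delta; only genes are
  clustered.
* All simulator randomness flows from one integer seed; the cohort and the
  count matrix use offset seed streams so regenerating counts does not
  perturb the cohort draw.

## Known limitations

* The SY screen at raw p < 0.01 controls the per-gene error rate, not the
  FDR; with few true effects most flagged genes can be false — the
  simulation-based empirical-FDR checks quantify this under the study
  conditions, and the output table carries BH-adjusted p for readers who
  want the stricter view.
* The batch model assumes additive location and multiplicative scale
  effects on the log2 scale with no batch × biology interaction, and the
  pipeline applies it without protecting biological covariates.
* The Fisher and rank-sum implementations target 2×2 tables and two-group
  comparisons only, which is all the balance table needs.
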