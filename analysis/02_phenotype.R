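#!/usr/bin/env Rscript
# Step 2: score the skin-youthfulness phenotype.
#
# Computes each subject's skin age score (median of rater scores), delta
# (chronological age minus SAS) and r_delta (residual of delta regressed on
# age), classifies subjects (young < 30; among ages >= 50, top 10% of
# r_delta = SY, lower half = non-SY), and checks covariate balance between
# the SY and non-SY groups.

library(skinyouth)

cohort <- read.csv("results/data/cohort.csv")
ph <- phenotype_cohort(cohort)
write_phenotype_csv(ph, "results/phenotype.csv")

fit <- attr(ph, "fit")
cat(sprintf("delta-on-age regression: slope %.3f y/y, intercept %.2f y\n",
            fit$slope, fit$intercept))
print(table(ph$class))

truth <- read.csv("results/data/truth_subjects.csv")
labelled <- ph$subject_id[ph$class == "SY"]
cat(sprintf("SY label agreement with ground truth: %.0f%%\n",
            100 * mean(labelled %in% truth$subject_id[truth$true_sy])))

bal <- covariate_balance(cohort, ph)
write.table(bal, "results/covariate_balance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("covariate balance (SY vs non-SY):\n")
print(bal, digits = 3)
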