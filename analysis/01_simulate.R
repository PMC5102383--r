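#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Generates a 122-subject cohort (ages 18-89, four blinded raters) with a
# latent skin-youthfulness trait, plus a 5000-gene 3'-seq count matrix with
# 100 injected age genes, 50 injected SY genes, two sequencing batches and
# log-normal library sizes. Inputs for all later steps are written under
# results/data/.

library(skinyouth)

cfg <- sim_config(seed = 20260925L)
sim <- simulate_study(cfg)
write_simulation(sim, "results/data")

cat(sprintf("cohort: %d subjects, ages %d-%d\n", nrow(sim$cohort),
            min(sim$cohort$age), max(sim$cohort$age)))
cat(sprintf("counts: %d genes x %d samples, median depth %.2fM reads\n",
            nrow(sim$matrix$values), ncol(sim$matrix$values),
            median(colSums(sim$matrix$values)) / 1e6))
cat(sprintf("ground truth: %d SY subjects, %d age genes, %d SY genes\n",
            length(sim$truth$true_sy_subjects), nrow(sim$truth$age_genes),
            nrow(sim$truth$sy_genes)))
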