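#!/usr/bin/env Rscript
# Step 3: preprocess the count matrix.
#
# Normalises each sample to 10 million mapped reads, keeps genes with mean
# normalised expression above 2, log2-transforms (pseudocount 1) and removes
# the sequencing-batch effect with the empirical-Bayes location/scale
# adjustment.

library(skinyouth)

counts <- read_expression_tsv("results/data/counts.tsv")
cohort <- read.csv("results/data/cohort.csv")

norm <- normalize_counts(counts)
kept <- filter_expressed(norm)
cat(sprintf("expressed genes: %d of %d pass mean > 2\n",
            nrow(kept$values), nrow(norm$values)))

lg <- log2_transform(kept)
pre <- mean(abs(rowMeans(lg$values[, cohort$batch == "B1"]) -
                rowMeans(lg$values[, cohort$batch == "B2"])))
adj <- batch_adjust(lg, cohort$batch)
expr <- adj$matrix
post <- mean(abs(rowMeans(expr$values[, cohort$batch == "B1"]) -
                 rowMeans(expr$values[, cohort$batch == "B2"])))
cat(sprintf("batch adjustment over %s: mean |batch mean diff| %.3f -> %.3f log2 units\n",
            paste(adj$model$batch_levels, collapse = "/"), pre, post))

write_expression_tsv(expr, "results/expression_preprocessed.tsv")
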