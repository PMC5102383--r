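Package: skinyouth
Title: Quantitative Skin-Youthfulness Phenotyping and Transcriptomic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing clinician-scored skin youthfulness together
    with 3'-end RNA-seq expression data. Builds a quantitative youthfulness
    phenotype from blinded skin-age scores (median score, delta = chronological
    age minus skin age score, and the residual of delta regressed on age),
    classifies subjects into young, skin-youthful (SY) and non-SY groups,
    preprocesses gene-by-sample count matrices (depth normalisation, expressed
    gene filtering, log2 transform, empirical-Bayes batch adjustment), detects
    age- and SY-associated genes with moderated t-statistics, runs covariate
    balance tests, and performs hypergeometric gene-set enrichment with
    cumulative set-level comparisons. Includes a cohort and count-matrix
    simulator with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
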