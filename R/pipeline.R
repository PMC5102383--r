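#' Assemble a pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' package defaults: SY top fraction 0.10, non-SY lower fraction 0.50, SY age
#' gate 50, young age gate 30, depth target 1e7, expression filter 2.0, age
#' FDR 0.01, SY raw-p cut 0.01, enrichment minimum change 0.3 and enrichment
#' FDR 0.1.
#'
#' @param counts,metadata,gmt input file paths (counts TSV, cohort CSV,
#'   optional GMT collection).
#' @param outdir output directory.
#' @param sy_top_fraction,nonsy_lower_fraction,sy_age_min,young_age_max
#'   phenotype-classification parameters.
#' @param target,min_mean,pseudocount preprocessing parameters.
#' @param age_fdr,sy_p_cut differential-expression thresholds.
#' @param min_change,enrich_fdr enrichment parameters.
#' @param seed top-level seed recorded in the run log.
#' @return A validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(counts, metadata, gmt = NULL, outdir = "results",
                            sy_top_fraction = 0.10,
                            nonsy_lower_fraction = 0.50,
                            sy_age_min = 50, young_age_max = 30,
                            target = 1e7, min_mean = 2.0, pseudocount = 1.0,
                            age_fdr = 0.01, sy_p_cut = 0.01,
                            min_change = 0.3, enrich_fdr = 0.1, seed = 1L) {
  cfg <- list(counts = counts, metadata = metadata, gmt = gmt,
              outdir = outdir, sy_top_fraction = sy_top_fraction,
              nonsy_lower_fraction = nonsy_lower_fraction,
              sy_age_min = sy_age_min, young_age_max = young_age_max,
              target = target, min_mean = min_mean, pseudocount = pseudocount,
              age_fdr = age_fdr, sy_p_cut = sy_p_cut,
              min_change = min_change, enrich_fdr = enrich_fdr,
              seed = as.integer(seed))
  fracs <- c(cfg$sy_top_fraction, cfg$nonsy_lower_fraction)
  if (any(fracs <= 0 | fracs > 1)) stop("fractions must lie in (0, 1]")
  if (cfg$age_fdr <= 0 || cfg$sy_p_cut <= 0) stop("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of \code{\link{pipeline_config}}; missing
#' keys take the defaults.
#'
#' @param path YAML file path.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

#' Run the full skin-youthfulness analysis pipeline
#'
#' Executes phenotype scoring, count preprocessing, age-gene and SY-gene
#' detection, optional gene-set enrichment, and heatmap ordering, writing
#' every result table and a run log (all parameters, the seed and a config
#' hash) under \code{config$outdir}. SY heatmap samples are ordered by
#' r_delta; genes are clustered (1 - Pearson, average linkage). Any stage
#' failure aborts the run, names the stage, and removes partial outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory results: \code{assignments},
#'   \code{balance}, \code{expr} (preprocessed matrix), \code{age},
#'   \code{sy}, \code{enrichment} (or NULL), \code{gene_order},
#'   \code{sample_order}, \code{outdir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  created <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  failed <- TRUE
  on.exit({
    if (failed) {
      unlink(written)
      if (created) unlink(outdir, recursive = TRUE)
    }
  })
  emit <- function(writer, obj, name) {
    path <- file.path(outdir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(config$seed)

  metadata <- stage("phenotype", {
    if (!file.exists(config$metadata)) {
      stop("metadata file not found: ", config$metadata)
    }
    utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  })
  assignments <- stage("phenotype", phenotype_cohort(
    metadata, sy_top_fraction = config$sy_top_fraction,
    nonsy_lower_fraction = config$nonsy_lower_fraction,
    sy_age_min = config$sy_age_min, young_age_max = config$young_age_max))
  emit(write_phenotype_csv, assignments, "phenotype.csv")
  balance <- stage("covariates", covariate_balance(metadata, assignments))
  emit(function(obj, path) utils::write.table(obj, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE),
       balance, "covariate_balance.tsv")

  expr <- stage("preprocess", {
    if (!file.exists(config$counts)) {
      stop("counts file not found: ", config$counts)
    }
    raw <- read_expression_tsv(config$counts)
    raw <- expression_matrix(
      raw$values[, assignments$subject_id, drop = FALSE], raw$stage)
    batches <- metadata$batch[match(assignments$subject_id,
                                    metadata$subject_id)]
    if (length(unique(batches)) < 2L) batches <- NULL
    preprocess_counts(raw, batches = batches, target = config$target,
                      min_mean = config$min_mean,
                      pseudocount = config$pseudocount)
  })

  ages <- assignments$age
  classes <- as.character(assignments$class)
  age_res <- stage("de-age", detect_age_genes(expr, ages, fdr = config$age_fdr))
  emit(write_de_tsv, age_res, "age_genes.tsv")
  sy_res <- stage("de-sy", detect_sy_genes(expr, ages, classes,
                                           p_cut = config$sy_p_cut))
  emit(write_de_tsv, sy_res, "sy_genes.tsv")

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- stage("gsea", {
      collection <- read_gmt(config$gmt)
      sel <- classes %in% c("SY", "non-SY")
      sub <- expression_matrix(expr$values[, sel, drop = FALSE], expr$stage)
      resid <- residualize_on_age(sub, ages[sel])
      ch <- call_changed_genes(resid, classes[sel],
                               min_change = config$min_change)
      enrich(ch$up, ch$down, ch$universe, collection, fdr = config$enrich_fdr)
    })
    emit(function(obj, path) utils::write.table(obj, path, sep = "\t",
                                                quote = FALSE,
                                                row.names = FALSE),
         enrichment, "enrichment.tsv")
  }

  cluster_out <- stage("cluster", {
    sig <- unique(c(sy_res$up, sy_res$down))
    gene_order <- NULL
    if (length(sig) >= 2L) {
      sub <- expr$values[sig, , drop = FALSE]
      keep <- apply(sub, 1L, stats::sd) > 0
      if (sum(keep) >= 2L) {
        dend <- hierarchical_cluster(
          expression_matrix(sub[keep, , drop = FALSE], expr$stage), "genes")
        emit(write_dendrogram, dend, "sy_gene_dendrogram.txt")
        gene_order <- rownames(sub[keep, , drop = FALSE])[dend$order]
      }
    }
    # heatmap sample order: ranked by r_delta (most youthful first)
    sample_order <- assignments$subject_id[order(-assignments$r_delta,
                                                 assignments$subject_id)]
    list(gene_order = gene_order, sample_order = sample_order)
  })
  writeLines(cluster_out$sample_order, file.path(outdir, "sample_order.txt"))
  written <- c(written, file.path(outdir, "sample_order.txt"))

  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c(
    paste0("config_hash=", config_hash(unclass(config))),
    paste0("seed=", config$seed),
    paste(names(unclass(config)),
          vapply(unclass(config), function(x)
            paste(format(x), collapse = ","), character(1)), sep = "=")
  ), log_path)
  written <- c(written, log_path)

  failed <- FALSE
  invisible(list(assignments = assignments, balance = balance, expr = expr,
                 age = age_res, sy = sy_res, enrichment = enrichment,
                 gene_order = cluster_out$gene_order,
                 sample_order = cluster_out$sample_order, outdir = outdir))
}
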