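#' Read a gene-set collection in GMT format
#'
#' GMT is the tab-delimited format of MSigDB distributions: one set per line,
#' fields = set name, description, then member gene ids. Duplicate members
#' within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @param name collection name (defaults to the file name).
#' @return A list of class \code{"gene_set_collection"}: \code{name},
#'   \code{sets} (named list of character vectors), \code{descriptions}.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(name = name, sets = list(),
                          descriptions = character()),
                     class = "gene_set_collection"))
  }
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' deduplicated", f[1]))
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    descs[[f[1]]] <- f[2]
  }
  structure(list(name = name, sets = sets, descriptions = descs),
            class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(s) {
    desc <- collection$descriptions[s]
    if (is.null(desc) || length(desc) == 0L || is.na(desc)) desc <- "na"
    paste(c(s, desc, collection$sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Call changed genes between SY and non-SY by mean difference
#'
#' On the age-residualized log2 scale, a gene is called "up" when its mean in
#' SY exceeds the non-SY mean by at least \code{min_change} log2 units and
#' "down" when it is lower by at least that much (inclusive thresholds). The
#' universe is every tested gene.
#'
#' @param m residualized \code{ExpressionMatrix}.
#' @param classes per-sample labels; \code{"SY"} and \code{"non-SY"} samples
#'   are compared (each group needs >= 2).
#' @param min_change minimum absolute log2 mean difference (default 0.3).
#' @return A list: \code{up}, \code{down} (gene id vectors), \code{universe},
#'   \code{delta} (named vector of mean differences).
#' @export
call_changed_genes <- function(m, classes, min_change = 0.3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (length(classes) != ncol(m$values)) {
    stop("'classes' must have one label per sample")
  }
  sy <- classes %in% "SY"
  nonsy <- classes %in% "non-SY"
  if (sum(sy) < 2L || sum(nonsy) < 2L) {
    stop("insufficient group: need >= 2 SY and >= 2 non-SY samples")
  }
  delta <- rowMeans(m$values[, sy, drop = FALSE]) -
    rowMeans(m$values[, nonsy, drop = FALSE])
  list(up = names(delta)[delta >= min_change],
       down = names(delta)[delta <= -min_change],
       universe = names(delta), delta = delta)
}

#' Hypergeometric over-representation of gene sets among changed genes
#'
#' For each set and each direction, tests whether the changed genes overlap
#' the set's members (intersected with the universe) more than expected under
#' sampling without replacement: one-sided hypergeometric upper-tail p.
#' Benjamini-Hochberg adjustment is applied across all set x direction tests;
#' results with adjusted p below \code{fdr} are returned ranked by p.
#'
#' @param up,down changed gene id vectors.
#' @param universe all tested gene ids (must contain \code{up} and
#'   \code{down}).
#' @param collection a \code{gene_set_collection}; sets disjoint from the
#'   universe are skipped with a warning.
#' @param fdr adjusted-p threshold (default 0.1); use \code{Inf} to keep all.
#' @return Data frame: set, direction, n_set_in_universe, n_changed,
#'   n_overlap, p, fdr, members (comma-separated overlap ids), ranked by p.
#' @export
enrich <- function(up, down, universe, collection, fdr = 0.1) {
  if (length(universe) == 0L) stop("invalid input: empty universe")
  if (!all(c(up, down) %in% universe)) {
    stop("invalid input: changed genes must be contained in the universe")
  }
  changed <- list(up = unique(up), down = unique(down))
  rows <- list()
  for (s in names(collection$sets)) {
    members <- intersect(collection$sets[[s]], universe)
    if (length(members) == 0L) {
      warning("set '", s, "' has no members in the universe; skipped")
      next
    }
    for (dir in c("up", "down")) {
      ch <- changed[[dir]]
      k <- length(intersect(members, ch))
      # P(overlap >= k) drawing |changed| genes from the universe
      p <- stats::phyper(k - 1L, length(members),
                         length(universe) - length(members),
                         length(ch), lower.tail = FALSE)
      rows[[paste(s, dir)]] <- data.frame(
        set = s, direction = dir,
        n_set_in_universe = length(members), n_changed = length(ch),
        n_overlap = k, p = p,
        members = paste(sort(intersect(members, ch)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(set = character(), direction = character(),
                      n_set_in_universe = integer(), n_changed = integer(),
                      n_overlap = integer(), p = numeric(), fdr = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set, out$direction), ]
  rownames(out) <- NULL
  out[out$fdr < fdr, , drop = FALSE]
}

#' Cumulative set-level expression comparison between SY and non-SY
#'
#' For every member gene of a set, computes its mean residualized expression
#' in the SY and in the non-SY group, returns the two empirical CDFs over
#' member genes (the cumulative-plot curves), and tests the paired per-gene
#' differences with a two-sided Wilcoxon signed-rank test (or a two-sample
#' Kolmogorov-Smirnov test with \code{method = "ks"}).
#'
#' @param m residualized \code{ExpressionMatrix}.
#' @param classes per-sample labels with \code{"SY"} and \code{"non-SY"}.
#' @param set_members gene ids of the set; at least 5 must be present in the
#'   matrix.
#' @param method \code{"signed_rank"} (default) or \code{"ks"}.
#' @return A list: \code{ecdf_sy}, \code{ecdf_nonsy} (functions),
#'   \code{means} (data frame gene_id, mean_sy, mean_nonsy), \code{test}
#'   (an \code{"sy_test"}).
#' @export
cumulative_set_test <- function(m, classes, set_members,
                                method = c("signed_rank", "ks")) {
  method <- match.arg(method)
  present <- intersect(set_members, rownames(m$values))
  if (length(present) < 5L) {
    stop("insufficient set: fewer than 5 member genes present in the matrix")
  }
  sy <- classes %in% "SY"
  nonsy <- classes %in% "non-SY"
  if (sum(sy) < 2L || sum(nonsy) < 2L) {
    stop("insufficient group: need >= 2 SY and >= 2 non-SY samples")
  }
  mean_sy <- rowMeans(m$values[present, sy, drop = FALSE])
  mean_nonsy <- rowMeans(m$values[present, nonsy, drop = FALSE])
  test <- if (method == "signed_rank") {
    if (all(mean_sy == mean_nonsy)) {
      # no non-zero paired differences: nothing to rank, no evidence
      sy_test(0, 1, method = "Wilcoxon signed-rank test (paired per-gene means)")
    } else {
      ht <- suppressWarnings(stats::wilcox.test(mean_sy, mean_nonsy,
                                                paired = TRUE))
      sy_test(unname(ht$statistic), ht$p.value,
              method = "Wilcoxon signed-rank test (paired per-gene means)")
    }
  } else {
    ht <- suppressWarnings(stats::ks.test(mean_sy, mean_nonsy))
    sy_test(unname(ht$statistic), ht$p.value,
            method = "Two-sample Kolmogorov-Smirnov test")
  }
  list(ecdf_sy = stats::ecdf(mean_sy), ecdf_nonsy = stats::ecdf(mean_nonsy),
       means = data.frame(gene_id = present, mean_sy = unname(mean_sy),
                          mean_nonsy = unname(mean_nonsy),
                          stringsAsFactors = FALSE),
       test = test)
}
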