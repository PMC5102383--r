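#' Expression matrix with a processing-stage tag
#'
#' A light container for a gene x sample matrix of expression values that
#' records how far along the preprocessing pipeline the values are. Stages
#' advance strictly in the order \code{raw} (counts) -> \code{normalized}
#' (counts per 10 million mapped reads) -> \code{log2} -> \code{batch_adjusted},
#' and the preprocessing functions refuse to run out of order.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Must carry
#'   rownames (gene ids) and colnames (sample ids).
#' @param stage character scalar, one of \code{"raw"}, \code{"normalized"},
#'   \code{"log2"}, \code{"batch_adjusted"}.
#' @return An object of class \code{"ExpressionMatrix"}: a list with elements
#'   \code{values} and \code{stage}.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), "raw")
#' gene_ids(m)
#' @export
expression_matrix <- function(values, stage = c("raw", "normalized", "log2",
                                                "batch_adjusted")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("'values' must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (stage %in% c("raw", "normalized") && any(values < 0)) {
    stop("negative values are not allowed at stage '", stage, "'")
  }
  structure(list(values = values, stage = stage), class = "ExpressionMatrix")
}

.stage_order <- c(raw = 1L, normalized = 2L, log2 = 3L, batch_adjusted = 4L)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param m an \code{ExpressionMatrix}.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

# Stop unless `m` is at exactly the stage a pipeline step expects.
assert_stage <- function(m, expected, caller) {
  if (!inherits(m, "ExpressionMatrix")) {
    stop(caller, "() expects an ExpressionMatrix")
  }
  if (!m$stage %in% expected) {
    stop(sprintf("%s() expects stage %s but got '%s' (stages advance raw -> normalized -> log2 -> batch_adjusted)",
                 caller, paste(sQuote(expected), collapse = " or "), m$stage))
  }
  invisible(m)
}

#' Read or write an expression matrix as tab-separated text
#'
#' The on-disk format is a gene x sample TSV with a header row of sample ids,
#' gene ids in the first column, and a leading \code{#stage=} comment line
#' recording the processing stage.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param path file path.
#' @return \code{read_expression_tsv} returns an \code{ExpressionMatrix};
#'   \code{write_expression_tsv} returns \code{path} invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#stage=", m$stage), con)
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- "raw"
  if (startsWith(first, "#stage=")) stage <- sub("^#stage=", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_matrix(vals, stage)
}
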