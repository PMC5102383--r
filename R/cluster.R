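#' Agglomerative clustering under correlation distance
#'
#' Hierarchical clustering with distance 1 - Pearson r and average linkage,
#' the conventional choice for expression heatmap ordering. Items are genes
#' (rows) or samples (columns). Items constant across the other axis have an
#' undefined correlation and raise an error.
#'
#' @param m an \code{ExpressionMatrix} or plain numeric matrix.
#' @param axis \code{"genes"} (cluster rows, default) or \code{"samples"}.
#' @return A list of class \code{"sy_dendrogram"}: \code{merge},
#'   \code{height}, \code{order} (leaf order), \code{labels}, and the
#'   underlying \code{hclust} object.
#' @export
hierarchical_cluster <- function(m, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  vals <- if (inherits(m, "ExpressionMatrix")) m$values else m
  x <- if (axis == "genes") vals else t(vals)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("undefined distance: constant item(s) under correlation metric: ",
         paste(utils::head(rownames(x)[sds == 0], 5), collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "sy_dendrogram")
}

#' Write a dendrogram's nested leaf order
#'
#' Serialises the merge tree as a Newick-style nested string (heights as
#' branch annotations) plus the flat leaf order, one label per line after the
#' tree line.
#'
#' @param dend an \code{"sy_dendrogram"}.
#' @param path output path.
#' @export
write_dendrogram <- function(dend, path) {
  nested <- function(i) {
    if (i < 0) return(dend$labels[-i])
    kids <- dend$merge[i, ]
    sprintf("(%s,%s):%.6g", nested(kids[1]), nested(kids[2]), dend$height[i])
  }
  lines <- c(paste0(nested(nrow(dend$merge)), ";"), dend$labels[dend$order])
  writeLines(lines, path)
  invisible(path)
}
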