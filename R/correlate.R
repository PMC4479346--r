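#' Log2 transform with pseudo-count
#'
#' `x -> log2(x + 1)`, the transform used for all log-scale views of FPKM
#' data (scatter plots, heatmaps). Spearman correlations are unaffected by
#' it (monotone), so they are computed on raw values.
#'
#' @param values Non-negative numeric vector or matrix.
#' @return Transformed object of the same shape.
#' @export
log2_pseudo <- function(values) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  log2(values + 1)
}

#' Pairwise Spearman correlation of expression columns
#'
#' @param x An [expression_matrix()] or [tissue_profile()].
#' @param level `"sample"` correlates sample columns (only meaningful for an
#'   expression matrix); `"tissue"` first averages samples within tissues.
#' @return Correlation matrix of class `correlation_matrix` (symmetric, unit
#'   diagonal, entries in \[-1, 1\]). Ties receive average ranks.
#' @export
spearman_pairwise <- function(x, level = c("sample", "tissue")) {
  level <- match.arg(level)
  if (inherits(x, "expression_matrix")) {
    m <- if (level == "tissue") unclass(average_by_tissue(x)) else x$values
  } else if (inherits(x, "tissue_profile")) {
    if (level == "sample")
      stop("a tissue profile has no sample level", call. = FALSE)
    m <- unclass(x)
  } else stop("x must be an expression_matrix or tissue_profile", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 columns to correlate", call. = FALSE)
  constant <- apply(m, 2, function(col) diff(range(col)) == 0)
  if (any(constant))
    stop("constant column(s) make Spearman correlation undefined: ",
         paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
  rho <- stats::cor(m, method = "spearman")
  structure(rho, class = c("correlation_matrix", "matrix"))
}

validate_correlation_matrix <- function(corr) {
  m <- unclass(corr)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("correlation matrix not symmetric",
                                      call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) stop("diagonal must be 1", call. = FALSE)
  if (any(m < -1 - 1e-8 | m > 1 + 1e-8)) stop("entries outside [-1, 1]",
                                              call. = FALSE)
  invisible(m)
}

#' Hierarchical clustering of a correlation matrix
#'
#' Agglomerates with average linkage on the distance `1 - rho`. Labels are
#' put in alphabetical order before clustering so that ties in merge heights
#' resolve deterministically.
#'
#' @param corr A `correlation_matrix` from [spearman_pairwise()].
#' @return An [stats::hclust] tree.
#' @export
cluster_tissues <- function(corr) {
  m <- validate_correlation_matrix(corr)
  ord <- order(colnames(m))
  m <- m[ord, ord]
  d <- stats::as.dist(1 - m)
  stats::hclust(d, method = "average")
}

#' Serialize a dendrogram to a Newick file
#'
#' @param tree An [stats::hclust] tree (e.g. from [cluster_tissues()]).
#' @param path Output path; the tree is written as a Newick string with
#'   branch lengths.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Log-scale scatter data for a pair of columns
#'
#' Emits the `log2(x + 1)` coordinate pairs used in sample-vs-sample scatter
#' plots, together with their Spearman correlation (computed on raw values).
#'
#' @param x An [expression_matrix()].
#' @param col_a,col_b Sample ids.
#' @return List with `data` (data.frame gene_id, a, b on the log scale) and
#'   `spearman`.
#' @export
scatter_pair <- function(x, col_a, col_b) {
  stopifnot(inherits(x, "expression_matrix"))
  missing <- setdiff(c(col_a, col_b), colnames(x$values))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  a <- x$values[, col_a]
  b <- x$values[, col_b]
  list(data = data.frame(gene_id = rownames(x$values),
                         a = log2_pseudo(a), b = log2_pseudo(b),
                         stringsAsFactors = FALSE),
       spearman = stats::cor(a, b, method = "spearman"))
}
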