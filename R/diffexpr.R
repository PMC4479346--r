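#' Five-fold mean-FPKM differential expression between two sample groups
#'
#' The regional differential-expression rule: a gene is reported when the
#' larger of the two group mean FPKMs is at least `fold_threshold` times the
#' smaller one. To avoid infinite ratios the smaller mean is floored at
#' `floor` inside the ratio only; the reported means are unmodified. Exact
#' ties are never reported.
#'
#' @param x An [expression_matrix()].
#' @param samples_a,samples_b Disjoint non-empty character vectors of sample
#'   ids present in `x`.
#' @param genes Optional gene subset (defaults to all genes in `x`); the
#'   study applies the rule to a tissue's elevated gene set.
#' @param fold_threshold Fold threshold (default 5).
#' @param floor FPKM floor for the ratio denominator (default 0.1, one tenth
#'   of the detection cutoff).
#' @return data.frame with columns gene_id, mean_a, mean_b, fold, higher_in
#'   ("A" or "B"), containing only genes passing the rule, sorted by fold
#'   descending.
#' @export
fold_differential <- function(x, samples_a, samples_b, genes = NULL,
                              fold_threshold = 5, floor = 0.1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(samples_a) < 1 || length(samples_b) < 1)
    stop("both sample groups must be non-empty", call. = FALSE)
  if (length(intersect(samples_a, samples_b)))
    stop("sample groups overlap", call. = FALSE)
  missing <- setdiff(c(samples_a, samples_b), colnames(x$values))
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(genes)) genes <- rownames(x$values)
  bad <- setdiff(genes, rownames(x$values))
  if (length(bad))
    stop("unknown gene(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  if (!length(genes))
    return(data.frame(gene_id = character(), mean_a = numeric(),
                      mean_b = numeric(), fold = numeric(),
                      higher_in = character(), stringsAsFactors = FALSE))
  ma <- rowMeans(x$values[genes, samples_a, drop = FALSE])
  mb <- rowMeans(x$values[genes, samples_b, drop = FALSE])
  hi <- pmax(ma, mb)
  lo <- pmin(ma, mb)
  fold <- hi / pmax(lo, floor)
  keep <- fold >= fold_threshold & ma != mb
  out <- data.frame(gene_id = genes[keep],
                    mean_a = unname(ma[keep]),
                    mean_b = unname(mb[keep]),
                    fold = unname(fold[keep]),
                    higher_in = ifelse(ma[keep] > mb[keep], "A", "B"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count differential genes by direction
#'
#' @param results Output of [fold_differential()].
#' @return Named integer vector `c(A = ..., B = ...)`; the counts sum to the
#'   number of reported genes.
#' @export
split_by_direction <- function(results) {
  counts <- table(factor(results$higher_in, levels = c("A", "B")))
  stats::setNames(as.integer(counts), c("A", "B"))
}
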