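#' mRNA pool composition of a tissue
#'
#' Fraction of a tissue's total FPKM mass contributed by each of four gene
#' classes: mitochondrial housekeeping (expressed in all and flagged
#' mitochondrial), other expressed-in-all genes, genes elevated in the
#' tissue, and everything else (including genes elevated only elsewhere,
#' mixed and not-detected genes, whose small FPKM mass still counts).
#'
#' @param profile A [tissue_profile()].
#' @param classifications Output of [classify_matrix()] on the same genes.
#' @param tissue Tissue name.
#' @return List of class `pool_composition` with elements `tissue`,
#'   `fractions` (named numeric, sums to 1) and `n_genes` (named integer).
#' @export
pool_composition <- function(profile, classifications, tissue) {
  if (!tissue %in% colnames(profile))
    stop("unknown tissue: ", tissue, call. = FALSE)
  stopifnot(identical(classifications$gene_id, rownames(profile)))
  fpkm <- profile[, tissue]
  total <- sum(fpkm)
  if (total <= 0)
    stop("total FPKM mass in ", tissue, " is zero; composition undefined",
         call. = FALSE)
  sets <- split_tissue_sets(classifications$elevated_tissues)
  elevated_here <- classifications$category %in% ELEVATED_CATEGORIES &
    vapply(sets, function(s) tissue %in% s, logical(1))
  eia <- classifications$category == "expressed_in_all"
  cls <- ifelse(eia & classifications$is_mitochondrial, "mitochondrial",
         ifelse(eia, "expressed_in_all_other",
         ifelse(elevated_here, "elevated_in_tissue", "other")))
  lev <- c("mitochondrial", "expressed_in_all_other", "elevated_in_tissue",
           "other")
  f <- factor(cls, levels = lev)
  mass <- vapply(split(fpkm, f), sum, numeric(1))
  structure(list(tissue = tissue,
                 fractions = mass / total,
                 n_genes = stats::setNames(as.integer(table(f)), lev)),
            class = "pool_composition")
}

#' @export
print.pool_composition <- function(x, ...) {
  cat(sprintf("<pool_composition> %s\n", x$tissue))
  for (cl in names(x$fractions))
    cat(sprintf("  %-28s %6.1f%%  (%d genes)\n", cl, 100 * x$fractions[[cl]],
                x$n_genes[[cl]]))
  invisible(x)
}

#' Convert a pool composition to a data.frame
#'
#' @param x A `pool_composition`.
#' @param ... Unused.
#' @return data.frame with columns tissue, class, fraction, n_genes.
#' @export
as.data.frame.pool_composition <- function(x, ...) {
  data.frame(tissue = x$tissue,
             class = names(x$fractions),
             fraction = unname(x$fractions),
             n_genes = unname(x$n_genes),
             stringsAsFactors = FALSE)
}

#' Most abundant genes in a tissue
#'
#' @param profile A [tissue_profile()].
#' @param tissue Tissue name.
#' @param n Number of genes to return (>= 1); capped at the gene total.
#' @return data.frame (gene_id, fpkm) sorted by FPKM descending, ties broken
#'   by gene id ascending.
#' @export
top_abundant <- function(profile, tissue, n = 10L) {
  if (!tissue %in% colnames(profile))
    stop("unknown tissue: ", tissue, call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  fpkm <- profile[, tissue]
  ord <- order(-fpkm, rownames(profile))
  keep <- ord[seq_len(min(n, length(ord)))]
  data.frame(gene_id = rownames(profile)[keep],
             fpkm = unname(fpkm[keep]),
             stringsAsFactors = FALSE)
}
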