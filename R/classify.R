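#' Classification parameters
#'
#' Thresholds of the six-category specificity scheme. The detection cutoff of
#' 1 FPKM corresponds roughly to one mRNA molecule per average cell; the
#' fold threshold of 5 defines enrichment and enhancement; group enrichment
#' searches tissue groups of size 2 to 7.
#'
#' @param detection_cutoff FPKM detection threshold (> 0). Default 1.
#' @param fold_threshold Fold-change threshold (> 1). Default 5.
#' @param group_min,group_max Bounds on the size of an enriched tissue group;
#'   `2 <= group_min <= group_max` and `group_max` must stay below the number
#'   of tissues in the panel. Defaults 2 and 7.
#' @param group_statistic How a group's expression level is summarised when
#'   compared against the maximum of the remaining tissues: `"mean"` (the
#'   group's mean FPKM, default) or `"min"` (every member individually must
#'   clear the fold threshold).
#' @return A list of class `classification_params`.
#' @export
classification_params <- function(detection_cutoff = 1,
                                  fold_threshold = 5,
                                  group_min = 2L,
                                  group_max = 7L,
                                  group_statistic = c("mean", "min")) {
  group_statistic <- match.arg(group_statistic)
  if (detection_cutoff <= 0) stop("detection_cutoff must be > 0", call. = FALSE)
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  group_min <- as.integer(group_min); group_max <- as.integer(group_max)
  if (group_min < 2L || group_min > group_max)
    stop("need 2 <= group_min <= group_max", call. = FALSE)
  structure(list(detection_cutoff = detection_cutoff,
                 fold_threshold = fold_threshold,
                 group_min = group_min,
                 group_max = group_max,
                 group_statistic = group_statistic),
            class = "classification_params")
}

check_panel_size <- function(n_tissues, params) {
  if (params$group_max >= n_tissues)
    stop("group_max (", params$group_max,
         ") must be smaller than the number of tissues (", n_tissues, ")",
         call. = FALSE)
}

#' Average samples within each tissue
#'
#' Collapses a gene x sample FPKM matrix to a gene x tissue profile by the
#' arithmetic mean of each tissue's samples.
#'
#' @param x An [expression_matrix()].
#' @return A [tissue_profile()] whose columns follow the order of first
#'   appearance of each tissue among the samples.
#' @export
average_by_tissue <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  tissues <- unique(unname(x$sample_tissue))
  prof <- vapply(tissues, function(t) {
    cols <- names(x$sample_tissue)[x$sample_tissue == t]
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (nrow(x$values) == 1L) prof <- matrix(prof, nrow = 1,
                                           dimnames = list(rownames(x$values), tissues))
  tissue_profile(prof)
}

#' Tissue-specific score
#'
#' A tissue's FPKM divided by the maximum FPKM over all other tissues.
#' Conventions: 0/0 is 0; positive/0 is `Inf`.
#'
#' @param profile_row Named numeric vector of per-tissue FPKM (>= 2 tissues).
#' @param tissue Tissue name to score.
#' @return Non-negative number, possibly `Inf`.
#' @export
tissue_specific_score <- function(profile_row, tissue) {
  if (!tissue %in% names(profile_row))
    stop("unknown tissue: ", tissue, call. = FALSE)
  x <- profile_row[[tissue]]
  others <- max(profile_row[names(profile_row) != tissue])
  if (others == 0) {
    if (x == 0) return(0)
    return(Inf)
  }
  x / others
}

group_level <- function(sorted_values, k, statistic) {
  if (statistic == "mean") mean(sorted_values[seq_len(k)])
  else sorted_values[k]  # descending sort: k-th value is the group minimum
}

#' Search for an enriched tissue group
#'
#' Finds the smallest group size k in `[group_min, group_max]` such that the
#' k tissues with highest FPKM are, as a group, at least `fold_threshold`
#' above the maximum FPKM of all remaining tissues and at least at the
#' detection cutoff. Scanning only the top-k set is exact: if any size-k
#' group satisfies the rule, the top-k group does, because swapping in a
#' higher-expressed tissue can only raise the group level and lower the
#' complement's maximum.
#'
#' @param profile_row Named numeric per-tissue FPKM vector.
#' @param params A [classification_params()].
#' @return Character vector of the group's tissue names, or `NULL` when no
#'   group of any admissible size qualifies.
#' @export
find_enriched_group <- function(profile_row, params = classification_params()) {
  n <- length(profile_row)
  check_panel_size(n, params)
  ord <- order(profile_row, decreasing = TRUE)
  v <- profile_row[ord]
  for (k in params$group_min:params$group_max) {
    lev <- group_level(v, k, params$group_statistic)
    if (lev >= params$detection_cutoff &&
        lev >= params$fold_threshold * max(v[(k + 1L):n])) {
      return(names(profile_row)[sort(ord[seq_len(k)])])
    }
  }
  NULL
}

#' Classify a single gene's tissue profile
#'
#' Applies the six-category rules in precedence order: tissue enriched
#' (one tissue at least fold x the maximum of all others, and detected),
#' group enriched (see [find_enriched_group()]), tissue enhanced (at least
#' fold x the mean over all tissues, and detected; every such tissue is
#' reported), expressed in all (detected everywhere), not detected
#' (detected nowhere), otherwise mixed.
#'
#' @param profile_row Named numeric per-tissue FPKM vector.
#' @param params A [classification_params()].
#' @return List with elements `category` (character scalar) and
#'   `elevated_tissues` (character vector, empty unless the category is one
#'   of the three elevated classes).
#' @export
classify_gene <- function(profile_row, params = classification_params()) {
  n <- length(profile_row)
  check_panel_size(n, params)
  cutoff <- params$detection_cutoff
  fold <- params$fold_threshold
  ord <- order(profile_row, decreasing = TRUE)
  top <- profile_row[ord[1L]]
  second <- profile_row[ord[2L]]
  if (top >= cutoff && top >= fold * second) {
    return(list(category = "tissue_enriched",
                elevated_tissues = names(profile_row)[ord[1L]]))
  }
  grp <- find_enriched_group(profile_row, params)
  if (!is.null(grp)) {
    return(list(category = "group_enriched", elevated_tissues = grp))
  }
  panel_mean <- mean(profile_row)
  enh <- profile_row >= cutoff & profile_row >= fold * panel_mean
  if (any(enh)) {
    return(list(category = "tissue_enhanced",
                elevated_tissues = sort(names(profile_row)[enh])))
  }
  detected <- profile_row >= cutoff
  if (all(detected))
    return(list(category = "expressed_in_all", elevated_tissues = character()))
  if (!any(detected))
    return(list(category = "not_detected", elevated_tissues = character()))
  list(category = "mixed", elevated_tissues = character())
}

row_scores <- function(profile_row) {
  # score(t) = x_t / max(others); vectorised via the two largest values
  ord <- order(profile_row, decreasing = TRUE)
  m1 <- profile_row[ord[1L]]
  m2 <- profile_row[ord[2L]]
  denom <- rep(m1, length(profile_row))
  denom[ord[1L]] <- m2
  s <- ifelse(denom == 0, ifelse(profile_row > 0, Inf, 0),
              profile_row / denom)
  stats::setNames(as.numeric(s), names(profile_row))
}

#' Classify every gene of a tissue profile
#'
#' Runs [classify_gene()] over all genes, attaches the mitochondrial flag
#' from the annotation, and fills per-tissue tissue-specific scores.
#'
#' @param profile A [tissue_profile()].
#' @param annotation Optional data.frame with columns gene_id, gene_name,
#'   is_mitochondrial (as returned by [read_gene_annotation()]). Genes absent
#'   from the annotation are flagged non-mitochondrial with a warning.
#' @param params A [classification_params()].
#' @return data.frame with one row per gene: `gene_id`, `gene_name`,
#'   `category`, `elevated_tissues` (semicolon-joined, alphabetical),
#'   `is_mitochondrial`, and one `score_<tissue>` column per tissue. The
#'   parameter set is attached as attribute `params`.
#' @export
classify_matrix <- function(profile, annotation = NULL,
                            params = classification_params()) {
  stopifnot(inherits(profile, "tissue_profile"))
  check_panel_size(ncol(profile), params)
  genes <- rownames(profile)
  tissues <- colnames(profile)
  n_genes <- length(genes)

  categories <- character(n_genes)
  elev <- character(n_genes)
  scores <- matrix(NA_real_, n_genes, length(tissues),
                   dimnames = list(genes, paste0("score_", tissues)))
  for (i in seq_len(n_genes)) {
    row <- profile[i, ]
    cl <- classify_gene(row, params)
    categories[i] <- cl$category
    elev[i] <- paste(sort(cl$elevated_tissues), collapse = ";")
    scores[i, ] <- row_scores(row)
  }

  gene_name <- genes
  is_mito <- rep(FALSE, n_genes)
  if (!is.null(annotation)) {
    idx <- match(genes, annotation$gene_id)
    unknown <- is.na(idx)
    if (any(unknown))
      warning(sum(unknown), " gene(s) missing from annotation; ",
              "treated as non-mitochondrial", call. = FALSE)
    gene_name[!unknown] <- annotation$gene_name[idx[!unknown]]
    is_mito[!unknown] <- annotation$is_mitochondrial[idx[!unknown]]
  }

  out <- data.frame(gene_id = genes,
                    gene_name = gene_name,
                    category = categories,
                    elevated_tissues = elev,
                    is_mitochondrial = is_mito,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "tissues") <- tissues
  out
}

classification_tissues <- function(classifications) {
  tissues <- attr(classifications, "tissues")
  if (is.null(tissues)) {
    sc <- grep("^score_", names(classifications), value = TRUE)
    tissues <- sub("^score_", "", sc)
  }
  tissues
}

split_tissue_sets <- function(joined) strsplit(joined, ";", fixed = TRUE)

#' Genes elevated in a tissue
#'
#' Tissue enriched, group enriched and tissue enhanced genes together form
#' the tissue-elevated set of a tissue.
#'
#' @param classifications Output of [classify_matrix()].
#' @param tissue Tissue name.
#' @return Character vector of gene ids.
#' @export
elevated_genes <- function(classifications, tissue) {
  tissues <- classification_tissues(classifications)
  if (!tissue %in% tissues)
    stop("unknown tissue: ", tissue, call. = FALSE)
  sets <- split_tissue_sets(classifications$elevated_tissues)
  hit <- classifications$category %in% ELEVATED_CATEGORIES &
    vapply(sets, function(s) tissue %in% s, logical(1))
  classifications$gene_id[hit]
}

#' Per-tissue classification summary (pie-chart view)
#'
#' Partitions all genes, from one tissue's vantage point, into: not detected
#' in the tissue, elevated in the tissue, expressed in all (split into
#' mitochondrial and other), and the remainder (detected in the tissue but
#' neither elevated there nor expressed in all). Also reports the fraction
#' of genes detected (FPKM >= cutoff) in the tissue.
#'
#' @param classifications Output of [classify_matrix()].
#' @param profile The [tissue_profile()] the classification was computed on.
#' @param tissue Tissue name.
#' @param params A [classification_params()].
#' @return List with `counts` (named integer vector over the five slices,
#'   summing to the number of genes) and `detected_fraction`.
#' @export
tissue_view <- function(classifications, profile, tissue,
                        params = classification_params()) {
  if (!tissue %in% colnames(profile))
    stop("unknown tissue: ", tissue, call. = FALSE)
  stopifnot(identical(classifications$gene_id, rownames(profile)))
  fpkm <- profile[, tissue]
  detected <- fpkm >= params$detection_cutoff
  sets <- split_tissue_sets(classifications$elevated_tissues)
  elevated_here <- classifications$category %in% ELEVATED_CATEGORIES &
    vapply(sets, function(s) tissue %in% s, logical(1))
  eia <- classifications$category == "expressed_in_all"
  slice <- ifelse(!detected, "not_detected_in_tissue",
           ifelse(elevated_here, "elevated_in_tissue",
           ifelse(eia & classifications$is_mitochondrial, "expressed_in_all_mitochondrial",
           ifelse(eia, "expressed_in_all_other", "other_detected"))))
  lev <- c("not_detected_in_tissue", "elevated_in_tissue",
           "expressed_in_all_mitochondrial", "expressed_in_all_other",
           "other_detected")
  counts <- table(factor(slice, levels = lev))
  list(counts = stats::setNames(as.integer(counts), lev),
       detected_fraction = mean(detected))
}

#' Tabulate category counts
#'
#' @param classifications Output of [classify_matrix()].
#' @return Named integer vector over the six categories.
#' @export
category_counts <- function(classifications) {
  counts <- table(factor(classifications$category, levels = ALL_CATEGORIES))
  stats::setNames(as.integer(counts), ALL_CATEGORIES)
}
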