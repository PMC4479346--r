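#' tissuespec: tissue-specificity classification from FPKM matrices
#'
#' Tools to classify genes by their expression pattern across a panel of
#' tissues (six categories: tissue enriched, group enriched, tissue enhanced,
#' expressed in all, mixed, not detected), and downstream summaries built on
#' that classification: tissue-specific scores, mRNA pool composition,
#' fold-change differential expression, Spearman correlation / clustering and
#' an enrichment-combination network. A synthetic generator plants genes of
#' every category with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

ELEVATED_CATEGORIES <- c("tissue_enriched", "group_enriched", "tissue_enhanced")
ALL_CATEGORIES <- c(ELEVATED_CATEGORIES, "expressed_in_all", "mixed", "not_detected")

#' Construct an expression matrix object
#'
#' Bundles a gene x sample FPKM matrix with its sample-to-tissue assignment
#' and validates the container invariants: all values finite and
#' non-negative, no duplicate gene or sample identifiers, and every sample
#' mapped to exactly one tissue.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). FPKM units.
#' @param sample_tissue Named character vector mapping sample id -> tissue
#'   name; names must cover every column of `values`.
#' @return An object of class `expression_matrix` with elements `values`
#'   (the matrix) and `sample_tissue` (the map, ordered as the columns).
#' @export
expression_matrix <- function(values, sample_tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("expression matrix contains negative FPKM values", call. = FALSE)
  missing_map <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing_map))
    stop("samples absent from the sample-to-tissue map: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  sample_tissue <- sample_tissue[colnames(values)]
  if (any(is.na(sample_tissue)) || !all(nzchar(sample_tissue)))
    stop("every sample must map to a non-empty tissue name", call. = FALSE)
  structure(list(values = values,
                 sample_tissue = sample_tissue),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_tissue))))
  invisible(x)
}

#' Construct a tissue profile (gene x tissue average FPKM)
#'
#' @param values Numeric matrix, genes in rows, tissues in columns
#'   (colnames = tissue names). Must have at least 2 tissues.
#' @return Object of class `tissue_profile` (a validated matrix).
#' @export
tissue_profile <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and tissue names as colnames",
         call. = FALSE)
  if (ncol(values) < 2)
    stop("a tissue profile needs at least 2 tissues", call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate gene or tissue identifiers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("tissue profile values must be finite and >= 0", call. = FALSE)
  structure(values, class = c("tissue_profile", "matrix"))
}

#' @export
print.tissue_profile <- function(x, ...) {
  cat(sprintf("<tissue_profile> %d genes x %d tissues\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a gene x sample FPKM matrix with its sample map
#'
#' The matrix file is tab-separated with a header row of sample ids and one
#' row per gene whose first column is the gene id. The sample map is a
#' two-column TSV (`sample_id`, `tissue`). Samples present in the matrix but
#' absent from the map are an error.
#'
#' @param matrix_path Path to the FPKM TSV.
#' @param sample_map_path Path to the sample map TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, sample_map_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("FPKM matrix needs a gene id column plus at least one sample",
         call. = FALSE)
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", matrix_path, call. = FALSE)
  vals <- raw[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric FPKM column(s): ",
         paste(names(vals)[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  map <- utils::read.delim(sample_map_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue")
  if (!all(need %in% names(map)))
    stop("sample map must have columns sample_id and tissue", call. = FALSE)
  if (anyDuplicated(map$sample_id))
    stop("duplicate sample ids in sample map", call. = FALSE)
  st <- stats::setNames(as.character(map$tissue), as.character(map$sample_id))
  expression_matrix(m, st)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `gene_name`, `is_mitochondrial`
#' (0/1). One record per gene.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with columns gene_id, gene_name, is_mitochondrial
#'   (logical).
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character"))
  need <- c("gene_id", "gene_name", "is_mitochondrial")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns gene_id, gene_name, is_mitochondrial",
         call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "),
         call. = FALSE)
  ann$is_mitochondrial <- as.logical(as.integer(ann$is_mitochondrial))
  ann[, need]
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, UTF-8, '.' decimal separator, no row names.
#'
#' @param records data.frame with a fixed column schema.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame", call. = FALSE)
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, dec = ".",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write an expression matrix and its sample map to TSV files
#'
#' Inverse of [read_expression_matrix()]: gene ids in a `gene_id` first
#' column, one column per sample; the map as (`sample_id`, `tissue`).
#'
#' @param x An [expression_matrix()].
#' @param matrix_path,sample_map_path Output paths.
#' @export
write_expression_matrix <- function(x, matrix_path, sample_map_path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, matrix_path)
  map <- data.frame(sample_id = names(x$sample_tissue),
                    tissue = unname(x$sample_tissue),
                    stringsAsFactors = FALSE)
  write_table(map, sample_map_path)
  invisible(c(matrix_path, sample_map_path))
}
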