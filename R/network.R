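#' Enrichment-combination network
#'
#' Bipartite graph linking tissue-combination nodes to tissue nodes. Genes
#' that are tissue enriched or group enriched and whose enriched tissue set
#' intersects the focus tissues are grouped by their exact enriched tissue
#' combination; each distinct combination becomes one node whose `count` is
#' the number of genes and whose `size` is the square root of that count.
#' Tissue-enhanced genes are excluded: the network shows enrichment only.
#'
#' @param classifications Output of [classify_matrix()].
#' @param focus Non-empty character vector of focus tissues.
#' @return An [igraph::graph] with vertex attributes `type` ("combination"
#'   or "tissue"), `count` and `size` (both NA on tissue nodes), and an edge
#'   from each combination node to every member tissue.
#' @export
build_network <- function(classifications, focus) {
  if (!length(focus)) stop("focus tissue set must be non-empty", call. = FALSE)
  enriched <- classifications$category %in% c("tissue_enriched", "group_enriched")
  sets <- split_tissue_sets(classifications$elevated_tissues)
  keep <- enriched & vapply(sets, function(s) any(focus %in% s), logical(1))
  combos <- vapply(sets[keep], function(s) paste(sort(s), collapse = ";"),
                   character(1))
  tab <- table(combos)
  if (!length(tab)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  combo_names <- names(tab)
  member_sets <- split_tissue_sets(combo_names)
  tissues <- sort(unique(unlist(member_sets)))
  # vertex names must be unique, and a single-tissue combination would
  # otherwise collide with its tissue node; the raw combination string is
  # kept in the `combination` attribute
  combo_ids <- paste0("genes|", combo_names)
  vertices <- data.frame(
    name = c(combo_ids, tissues),
    type = c(rep("combination", length(combo_ids)),
             rep("tissue", length(tissues))),
    combination = c(combo_names, rep(NA_character_, length(tissues))),
    count = c(as.integer(tab), rep(NA_integer_, length(tissues))),
    size = c(sqrt(as.integer(tab)), rep(NA_real_, length(tissues))),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(seq_along(combo_ids), function(i) {
    data.frame(from = combo_ids[i], to = member_sets[[i]],
               stringsAsFactors = FALSE)
  }))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Genes enriched in both of two tissues
#'
#' Tissue or group enriched genes whose enriched tissue set contains both
#' tissues (necessarily group enriched, since a tissue-enriched set has one
#' member). Tissue-enhanced genes do not qualify.
#'
#' @param classifications Output of [classify_matrix()].
#' @param tissue_a,tissue_b Distinct tissue names.
#' @return Character vector of gene ids.
#' @export
shared_enriched <- function(classifications, tissue_a, tissue_b) {
  if (identical(tissue_a, tissue_b))
    stop("tissues must be distinct", call. = FALSE)
  tissues <- classification_tissues(classifications)
  unknown <- setdiff(c(tissue_a, tissue_b), tissues)
  if (length(unknown))
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  enriched <- classifications$category %in% c("tissue_enriched", "group_enriched")
  sets <- split_tissue_sets(classifications$elevated_tissues)
  hit <- enriched & vapply(sets, function(s)
    tissue_a %in% s && tissue_b %in% s, logical(1))
  classifications$gene_id[hit]
}

#' Export a network as GraphML plus an edge-list TSV
#'
#' @param network Output of [build_network()].
#' @param graphml_path,edges_path Output paths.
#' @export
write_network <- function(network, graphml_path, edges_path) {
  igraph::write_graph(network, graphml_path, format = "graphml")
  el <- igraph::as_edgelist(network)
  write_table(data.frame(combination = sub("^genes\\|", "", el[, 1]),
                         tissue = el[, 2],
                         stringsAsFactors = FALSE), edges_path)
  invisible(c(graphml_path, edges_path))
}

#' Combination-node table of a network
#'
#' @param network Output of [build_network()].
#' @return data.frame with columns combination, count, size.
#' @export
network_nodes <- function(network) {
  if (igraph::vcount(network) == 0)
    return(data.frame(combination = character(), count = integer(),
                      size = numeric(), stringsAsFactors = FALSE))
  v <- igraph::as_data_frame(network, what = "vertices")
  v <- v[v$type == "combination", c("combination", "count", "size")]
  rownames(v) <- NULL
  v
}
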