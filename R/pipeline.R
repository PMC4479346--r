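stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic panel
#'
#' Orchestrates simulate -> classify -> composition -> differential
#' expression -> correlation/clustering -> network, writing every result
#' table under `out_dir` as TSV (plus a Newick dendrogram, a GraphML network
#' and a run-metadata file). All randomness flows from `config$seed`; re-runs
#' with the same configuration produce byte-identical outputs.
#'
#' The differential-expression stage contrasts the first half of the first
#' focus tissue's samples against the second half (the auricle-versus-
#' ventricle design of the study's cardiac samples), restricted to that
#' tissue's elevated genes.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param params A [classification_params()].
#' @param focus_tissues Tissues highlighted in the composition, tissue-view
#'   and network stages; default the two striated muscles.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(out_dir,
                         config = simulation_config(),
                         params = classification_params(),
                         focus_tissues = c("cardiac_muscle", "skeletal_muscle")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  pth <- function(f) file.path(out_dir, f)

  sim <- stage_try("simulate", {
    pr <- generate_profile(config)
    mat <- scatter_samples(pr$profile, config)
    write_expression_matrix(mat, pth("fpkm_matrix.tsv"), pth("sample_map.tsv"))
    write_table(pr$truth, pth("ground_truth.tsv"))
    write_table(truth_annotation(pr$truth), pth("gene_annotation.tsv"))
    list(profile_true = pr$profile, truth = pr$truth, matrix = mat)
  })
  paths$fpkm_matrix <- pth("fpkm_matrix.tsv")
  paths$sample_map <- pth("sample_map.tsv")
  paths$ground_truth <- pth("ground_truth.tsv")
  paths$gene_annotation <- pth("gene_annotation.tsv")

  cls <- stage_try("classify", {
    profile <- average_by_tissue(sim$matrix)
    cl <- classify_matrix(profile, truth_annotation(sim$truth), params)
    write_table(cl, pth("classification.tsv"))
    counts <- category_counts(cl)
    write_table(data.frame(category = names(counts), n = unname(counts)),
                pth("category_counts.tsv"))
    list(profile = profile, classifications = cl)
  })
  paths$classification <- pth("classification.tsv")
  paths$category_counts <- pth("category_counts.tsv")

  focus <- intersect(focus_tissues, colnames(cls$profile))
  if (!length(focus))
    stop("[composition] no focus tissue present in the panel", call. = FALSE)

  stage_try("composition", {
    comp <- do.call(rbind, lapply(focus, function(t)
      as.data.frame(pool_composition(cls$profile, cls$classifications, t))))
    write_table(comp, pth("pool_composition.tsv"))
    top <- do.call(rbind, lapply(focus, function(t) {
      ta <- top_abundant(cls$profile, t, 20L)
      cbind(tissue = t, ta)
    }))
    write_table(top, pth("top_abundant.tsv"))
    views <- do.call(rbind, lapply(focus, function(t) {
      v <- tissue_view(cls$classifications, cls$profile, t, params)
      data.frame(tissue = t, slice = names(v$counts), n = unname(v$counts),
                 detected_fraction = v$detected_fraction)
    }))
    write_table(views, pth("tissue_views.tsv"))
  })
  paths$pool_composition <- pth("pool_composition.tsv")
  paths$top_abundant <- pth("top_abundant.tsv")
  paths$tissue_views <- pth("tissue_views.tsv")

  stage_try("diffexp", {
    t1 <- focus[[1L]]
    samples <- names(sim$matrix$sample_tissue)[sim$matrix$sample_tissue == t1]
    if (length(samples) >= 2L) {
      half <- seq_len(length(samples) %/% 2L)
      res <- fold_differential(sim$matrix, samples[half], samples[-half],
                               genes = elevated_genes(cls$classifications, t1))
      write_table(res, pth("regional_diffexp.tsv"))
    } else {
      write_table(data.frame(gene_id = character(), mean_a = numeric(),
                             mean_b = numeric(), fold = numeric(),
                             higher_in = character()),
                  pth("regional_diffexp.tsv"))
    }
  })
  paths$regional_diffexp <- pth("regional_diffexp.tsv")

  stage_try("correlate", {
    rho_t <- spearman_pairwise(sim$matrix, level = "tissue")
    df <- data.frame(tissue = rownames(rho_t), as.data.frame(unclass(rho_t)),
                     check.names = FALSE)
    write_table(df, pth("tissue_spearman.tsv"))
    write_newick(cluster_tissues(rho_t), pth("tissue_dendrogram.nwk"))
  })
  paths$tissue_spearman <- pth("tissue_spearman.tsv")
  paths$tissue_dendrogram <- pth("tissue_dendrogram.nwk")

  stage_try("network", {
    net <- build_network(cls$classifications, focus)
    write_network(net, pth("enrichment_network.graphml"),
                  pth("enrichment_edges.tsv"))
  })
  paths$enrichment_network <- pth("enrichment_network.graphml")
  paths$enrichment_edges <- pth("enrichment_edges.tsv")

  stage_try("metadata", {
    files <- sort(unlist(paths))
    meta <- data.frame(
      key = c("seed", "n_tissues", "n_genes", "margin", "noise_sigma",
              "mito_pool_target", "detection_cutoff", "fold_threshold",
              "group_min", "group_max", "focus_tissues",
              paste0("md5_", basename(files))),
      value = c(config$seed, config$n_tissues, sum(config$planted_counts),
                config$margin, config$noise_sigma, config$mito_pool_target,
                params$detection_cutoff, params$fold_threshold,
                params$group_min, params$group_max,
                paste(focus, collapse = ";"),
                unname(tools::md5sum(files))),
      stringsAsFactors = FALSE)
    write_table(meta, pth("run_metadata.tsv"))
  })
  paths$run_metadata <- pth("run_metadata.tsv")

  invisible(paths)
}
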