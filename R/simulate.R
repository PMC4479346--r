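DEFAULT_TISSUES <- c(
  "cardiac_muscle", "skeletal_muscle", "cerebral_cortex", "adipose_tissue",
  "liver", "testis", "kidney", "lung", "spleen", "pancreas", "stomach",
  "colon", "small_intestine", "duodenum", "rectum", "esophagus", "prostate",
  "urinary_bladder", "gallbladder", "thyroid", "adrenal_gland", "lymph_node",
  "bone_marrow", "appendix", "ovary", "endometrium", "placenta", "skin")

default_planted_counts <- function() {
  c(tissue_enriched = 400L, group_enriched = 400L, tissue_enhanced = 400L,
    expressed_in_all = 1900L, mitochondrial = 150L, mixed = 1000L,
    not_detected = 750L)
}

#' Simulation configuration
#'
#' Describes a synthetic multi-tissue FPKM panel with planted specificity
#' structure: per-category gene counts, the multiplicative margin by which
#' planted genes clear their category's defining inequality, log-scale
#' sample noise, and the mitochondrial share of each tissue's mRNA pool.
#' Defaults emulate the study panel: 28 tissues, 3 samples per tissue,
#' 5,000 genes, margin 2, log2 noise SD 0.25 (giving same-tissue sample
#' rank correlations around 0.97) and a mitochondrial pool fraction of 0.3.
#'
#' @param n_tissues Number of tissues (default 28).
#' @param samples_per_tissue Scalar, or named integer vector per tissue
#'   (default 3).
#' @param planted_counts Named integer vector over
#'   `tissue_enriched, group_enriched, tissue_enhanced, expressed_in_all,
#'   mitochondrial, mixed, not_detected` (mitochondrial genes are
#'   housekeeping genes flagged mitochondrial). Default totals 5,000 genes.
#' @param margin Multiplicative slack (> 1) beyond the fold threshold with
#'   which planted genes satisfy their category rule. Default 2.
#' @param noise_sigma SD of the log2-scale multiplicative sample noise
#'   (default 0.25).
#' @param mito_pool_target Target fraction of each tissue's FPKM mass
#'   carried by the mitochondrial housekeeping block (default 0.3).
#' @param seed Integer seed; all randomness in [generate_profile()] and
#'   [scatter_samples()] derives from it.
#' @param params [classification_params()] whose cutoff/fold/group bounds
#'   the construction respects.
#' @param tissue_names Optional tissue names (length `n_tissues`).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 28L,
                              samples_per_tissue = 3L,
                              planted_counts = default_planted_counts(),
                              margin = 2.0,
                              noise_sigma = 0.25,
                              mito_pool_target = 0.3,
                              seed = 1L,
                              params = classification_params(),
                              tissue_names = NULL) {
  n_tissues <- as.integer(n_tissues)
  if (margin <= 1) stop("margin must be > 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (mito_pool_target < 0 || mito_pool_target >= 1)
    stop("mito_pool_target must lie in [0, 1)", call. = FALSE)
  check_panel_size(n_tissues, params)
  need <- names(default_planted_counts())
  if (!all(need %in% names(planted_counts)))
    stop("planted_counts must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  planted_counts <- vapply(planted_counts[need], as.integer, integer(1))
  if (any(planted_counts < 0)) stop("planted counts must be >= 0", call. = FALSE)
  if (mito_pool_target > 0 && planted_counts[["mitochondrial"]] == 0)
    stop("mito_pool_target > 0 requires mitochondrial genes", call. = FALSE)
  if (is.null(tissue_names)) {
    tissue_names <- if (n_tissues <= length(DEFAULT_TISSUES))
      DEFAULT_TISSUES[seq_len(n_tissues)]
    else c(DEFAULT_TISSUES,
           sprintf("tissue_%02d", seq_len(n_tissues - length(DEFAULT_TISSUES))))
  }
  if (length(tissue_names) != n_tissues || anyDuplicated(tissue_names))
    stop("tissue_names must be ", n_tissues, " unique names", call. = FALSE)
  if (length(samples_per_tissue) == 1L) {
    samples_per_tissue <- stats::setNames(
      rep(as.integer(samples_per_tissue), n_tissues), tissue_names)
  } else {
    if (!all(tissue_names %in% names(samples_per_tissue)))
      stop("samples_per_tissue must cover every tissue", call. = FALSE)
    samples_per_tissue <- vapply(samples_per_tissue[tissue_names],
                                 as.integer, integer(1))
  }
  if (any(samples_per_tissue < 1L))
    stop("every tissue needs at least one sample", call. = FALSE)
  structure(list(n_tissues = n_tissues,
                 samples_per_tissue = samples_per_tissue,
                 planted_counts = planted_counts,
                 margin = margin,
                 noise_sigma = noise_sigma,
                 mito_pool_target = mito_pool_target,
                 seed = as.integer(seed),
                 params = params,
                 tissue_names = tissue_names),
            class = "simulation_config")
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# Tissue-mean vector for one planted tissue_enhanced gene. The peak c must
# be >= margin*fold*panel_mean yet < fold*max(others): group_max "blocker"
# tissues are placed between c/fold and c so that neither the enriched rule
# nor any 2..group_max group qualifies. Solving the panel-mean identity for
# the blocker level bounds the feasible margin at roughly
# n / (fold * (1 + group_max/fold)); infeasible margins are a config error.
enhanced_gene_row <- function(n, target_idx, margin, params) {
  fold <- params$fold_threshold
  n_block <- params$group_max
  n_rest <- n - 1L - n_block
  r <- if (n_rest > 0) stats::runif(n_rest, 0.05, 0.3) else numeric()
  peak <- runif_log(1, 50, 150)
  blocker <- (n * peak / (margin * fold) - peak - sum(r)) / n_block
  if (blocker < 1.05 * peak / fold || blocker > 0.9 * peak)
    stop("margin ", margin, " is infeasible for planted tissue_enhanced ",
         "genes on a ", n, "-tissue panel (fold ", fold, "); reduce margin",
         call. = FALSE)
  row <- numeric(n)
  others <- setdiff(seq_len(n), target_idx)
  block_idx <- sample(others, n_block)
  rest_idx <- setdiff(others, block_idx)
  row[target_idx] <- peak
  row[block_idx] <- blocker
  row[rest_idx] <- r
  row
}

#' Generate a synthetic tissue profile with known ground truth
#'
#' Builds per-gene tissue-mean vectors that satisfy their planted category's
#' defining inequality with multiplicative slack `margin`: enriched genes sit
#' at `margin * fold * max(baseline)` over log-uniform \[1, 10\] baselines;
#' group-enriched genes place 2..group_max member tissues there; enhanced
#' genes clear `margin * fold * panel mean` while blocker tissues keep them
#' below the enriched and group rules; housekeeping genes are log-uniform
#' \[2, 10\] everywhere; mixed genes are detected in a random subset of
#' tissues with no elevation; not-detected genes stay below half the cutoff.
#' The mitochondrial housekeeping block is scaled per tissue so its share of
#' total FPKM mass equals `mito_pool_target` exactly (before noise), with
#' Zipf weights across its genes so one dominates, as MT-CO1 does in heart.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `profile` (a [tissue_profile()]) and `truth`
#'   (data.frame gene_id, category, elevated_tissues, is_mitochondrial).
#' @export
generate_profile <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_tissues
  tissues <- config$tissue_names
  params <- config$params
  fold <- params$fold_threshold
  cutoff <- params$detection_cutoff
  counts <- config$planted_counts
  m <- config$margin

  rows <- list(); cats <- list(); elevs <- list()
  add_block <- function(block, category, elevated) {
    rows[[length(rows) + 1L]] <<- block
    cats[[length(cats) + 1L]] <<- rep(category, nrow(block))
    elevs[[length(elevs) + 1L]] <<- elevated
  }

  if (counts[["tissue_enriched"]] > 0) {
    k <- counts[["tissue_enriched"]]
    block <- matrix(0, k, n)
    elev <- character(k)
    for (i in seq_len(k)) {
      t_idx <- ((i - 1L) %% n) + 1L
      b <- runif_log(n - 1L, 1, 10)
      block[i, -t_idx] <- b
      block[i, t_idx] <- m * fold * max(b)
      elev[i] <- tissues[t_idx]
    }
    add_block(block, "tissue_enriched", elev)
  }

  if (counts[["group_enriched"]] > 0) {
    k <- counts[["group_enriched"]]
    block <- matrix(0, k, n)
    elev <- character(k)
    for (i in seq_len(k)) {
      gsize <- sample(params$group_min:params$group_max, 1L)
      members <- sample.int(n, gsize)
      b <- runif_log(n - gsize, 1, 10)
      level <- m * fold * max(b)
      block[i, -members] <- b
      block[i, members] <- level * stats::runif(gsize, 1, 1.05)
      elev[i] <- paste(sort(tissues[members]), collapse = ";")
    }
    add_block(block, "group_enriched", elev)
  }

  if (counts[["tissue_enhanced"]] > 0) {
    k <- counts[["tissue_enhanced"]]
    block <- matrix(0, k, n)
    elev <- character(k)
    for (i in seq_len(k)) {
      t_idx <- ((i - 1L) %% n) + 1L
      block[i, ] <- enhanced_gene_row(n, t_idx, m, params)
      elev[i] <- tissues[t_idx]
    }
    add_block(block, "tissue_enhanced", elev)
  }

  if (counts[["expressed_in_all"]] > 0) {
    k <- counts[["expressed_in_all"]]
    block <- matrix(runif_log(k * n, 2, 10), k, n)
    add_block(block, "expressed_in_all", rep("", k))
  }

  if (counts[["mixed"]] > 0) {
    k <- counts[["mixed"]]
    block <- matrix(0, k, n)
    for (i in seq_len(k)) {
      d <- sample.int(n - 1L, 1L)
      det <- sample.int(n, d)
      block[i, det] <- stats::runif(d, 1.5, 2.0)
      block[i, -det] <- stats::runif(n - d, 0.5, 0.7)
    }
    add_block(block, "mixed", rep("", k))
  }

  if (counts[["not_detected"]] > 0) {
    k <- counts[["not_detected"]]
    block <- matrix(stats::runif(k * n, 0, cutoff / 2), k, n)
    add_block(block, "not_detected", rep("", k))
  }

  values <- do.call(rbind, rows)
  category <- unlist(cats)
  elevated <- unlist(elevs)
  is_mito <- rep(FALSE, length(category))

  # Mitochondrial housekeeping block: per-tissue mass chosen so its pool
  # share equals mito_pool_target exactly on the noiseless profile.
  if (counts[["mitochondrial"]] > 0) {
    k <- counts[["mitochondrial"]]
    p <- config$mito_pool_target
    other_mass <- colSums(values)
    if (any(other_mass <= 0))
      stop("cannot target a mitochondrial pool fraction on a tissue with ",
           "zero non-mitochondrial mass", call. = FALSE)
    w <- (1 / seq_len(k)); w <- w / sum(w)
    mito_mass <- other_mass * p / (1 - p)
    block <- outer(w, mito_mass)
    values <- rbind(values, block)
    category <- c(category, rep("expressed_in_all", k))
    elevated <- c(elevated, rep("", k))
    is_mito <- c(is_mito, rep(TRUE, k))
  }

  gene_ids <- sprintf("GENE%05d", seq_len(nrow(values)))
  dimnames(values) <- list(gene_ids, tissues)
  list(profile = tissue_profile(values),
       truth = data.frame(gene_id = gene_ids,
                          category = category,
                          elevated_tissues = elevated,
                          is_mitochondrial = is_mito,
                          stringsAsFactors = FALSE))
}

#' Scatter a tissue profile into per-sample FPKM values
#'
#' Each sample value is its tissue mean times `2^eps` with
#' `eps ~ Normal(0, noise_sigma^2)`, independent per gene and sample —
#' multiplicative log-normal noise, so replicate rank correlations stay high
#' as in real FPKM data. Deterministic given `config$seed`.
#'
#' @param profile A [tissue_profile()].
#' @param config The [simulation_config()] (sample layout, noise, seed).
#' @return An [expression_matrix()] with samples named `<tissue>_s<j>`.
#' @export
scatter_samples <- function(profile, config) {
  stopifnot(inherits(profile, "tissue_profile"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  tissues <- colnames(profile)
  missing <- setdiff(tissues, names(config$samples_per_tissue))
  if (length(missing))
    stop("config lacks sample counts for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cols <- list()
  sample_tissue <- character()
  for (t in tissues) {
    for (j in seq_len(config$samples_per_tissue[[t]])) {
      sid <- sprintf("%s_s%d", t, j)
      eps <- stats::rnorm(nrow(profile), 0, config$noise_sigma)
      cols[[sid]] <- profile[, t] * 2^eps
      sample_tissue[sid] <- t
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(profile)
  expression_matrix(values, sample_tissue)
}

#' Gene annotation table for a simulated data set
#'
#' @param truth Ground-truth table from [generate_profile()].
#' @return data.frame (gene_id, gene_name, is_mitochondrial) suitable for
#'   [classify_matrix()]; gene names are the ids.
#' @export
truth_annotation <- function(truth) {
  data.frame(gene_id = truth$gene_id,
             gene_name = truth$gene_id,
             is_mitochondrial = truth$is_mitochondrial,
             stringsAsFactors = FALSE)
}

#' Fraction of planted labels recovered by the classifier
#'
#' @param classifications Output of [classify_matrix()].
#' @param truth Ground-truth table from [generate_profile()].
#' @param check_tissues Also require the elevated tissue sets to match
#'   (default FALSE: categories only).
#' @return Fraction in \[0, 1\].
#' @export
recovery_rate <- function(classifications, truth, check_tissues = FALSE) {
  stopifnot(identical(classifications$gene_id, truth$gene_id))
  ok <- classifications$category == truth$category
  if (check_tissues)
    ok <- ok & classifications$elevated_tissues == truth$elevated_tissues
  mean(ok)
}
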