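# Shared fixtures and the independent brute-force oracle for the group
# search. Everything is built in code; no stored data files.

make_profile <- function(values, tissues = NULL, genes = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(tissues)) tissues <- sprintf("t%02d", seq_len(ncol(values)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  dimnames(values) <- list(genes, tissues)
  tissue_profile(values)
}

named_row <- function(values, tissues = NULL) {
  if (is.null(tissues)) tissues <- sprintf("t%02d", seq_along(values))
  stats::setNames(values, tissues)
}

make_matrix <- function(values, sample_tissue, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  rownames(values) <- genes
  colnames(values) <- names(sample_tissue)
  expression_matrix(values, sample_tissue)
}

# A 28-tissue row: value vector padded with `fill` up to 28 entries.
row28 <- function(head_values, fill = 1) {
  named_row(c(head_values, rep(fill, 28 - length(head_values))))
}

# Independent oracle: exhaustive search over every tissue subset of size
# group_min..group_max; TRUE iff any subset satisfies the group rule.
oracle_group_exists <- function(values, params) {
  n <- length(values)
  for (k in params$group_min:params$group_max) {
    cmb <- utils::combn(n, k)
    grp <- matrix(values[cmb], nrow = k)
    lev <- if (params$group_statistic == "mean") colMeans(grp)
           else apply(grp, 2, min)
    vm <- matrix(values, n, ncol(cmb))
    idx <- as.vector(cmb) + rep((seq_len(ncol(cmb)) - 1L) * n, each = k)
    vm[idx] <- -Inf
    cm <- vm[1, ]
    for (i in 2:n) cm <- pmax(cm, vm[i, ])
    if (any(lev >= params$detection_cutoff &
            lev >= params$fold_threshold * cm))
      return(TRUE)
  }
  FALSE
}

# Random per-tissue FPKM vector; roughly half the draws get a planted
# elevated subset so the oracle comparison sees both outcomes.
random_profile_vec <- function(n) {
  v <- 10^stats::runif(n, -1, 1.3)
  if (stats::runif(1) < 0.5) {
    k <- sample.int(min(7L, n - 1L), 1L)
    idx <- sample.int(n, k)
    v[idx] <- v[idx] * stats::runif(1, 2, 12)
  }
  v
}

small_sim_config <- function(seed = 7L, noise_sigma = 0.25, ...) {
  simulation_config(
    planted_counts = c(tissue_enriched = 56L, group_enriched = 40L,
                       tissue_enhanced = 28L, expressed_in_all = 150L,
                       mitochondrial = 20L, mixed = 80L, not_detected = 60L),
    noise_sigma = noise_sigma, seed = seed, ...)
}
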