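test_that("log2 pseudo-count transform hits its fixed points", {
  expect_equal(log2_pseudo(c(0, 1, 3)), c(0, 1, 2))
  expect_error(log2_pseudo(-1), ">= 0")
})

test_that("Spearman matches the rank-difference formula on small columns", {
  em <- make_matrix(cbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)),
                    c(s1 = "a", s2 = "b", s3 = "c"))
  rho <- spearman_pairwise(em, level = "sample")
  expect_equal(rho["s1", "s2"], 1.0)
  expect_equal(rho["s1", "s3"], -1.0)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 12/60 = 0.8
  em4 <- make_matrix(cbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
                     c(s1 = "a", s2 = "b"))
  expect_equal(spearman_pairwise(em4, level = "sample")["s1", "s2"], 0.8)
})

test_that("Spearman is invariant under monotone transforms and validates output", {
  set.seed(8)
  vals <- matrix(10^stats::runif(200 * 4, -1, 2), 200, 4)
  em <- make_matrix(vals, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
  rho <- spearman_pairwise(em, level = "sample")
  em_log <- make_matrix(log2_pseudo(vals),
                        c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
  expect_equal(unclass(spearman_pairwise(em_log, level = "sample")),
               unclass(rho))
  expect_equal(unclass(rho), t(unclass(rho)))
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_true(all(rho >= -1 & rho <= 1))
  # tissue level averages samples first
  rho_t <- spearman_pairwise(em, level = "tissue")
  expect_identical(colnames(rho_t), c("a", "b"))
})

test_that("constant columns raise an undefined-correlation error", {
  em <- make_matrix(cbind(c(1, 2, 3), c(5, 5, 5)),
                    c(s1 = "a", s2 = "b"))
  expect_error(spearman_pairwise(em, level = "sample"), "constant column")
  expect_error(spearman_pairwise(em, level = "sample"), "s2")
})

naive_average_linkage <- function(d) {
  # step-by-step agglomeration over the raw distance matrix
  labels <- lapply(colnames(d), identity)
  merges <- list()
  while (length(labels) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i >= j) next
      h <- mean(d[labels[[i]], labels[[j]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(labels[[best[1]]], labels[[best[2]]])),
           height = bh)
    labels[[best[1]]] <- c(labels[[best[1]]], labels[[best[2]]])
    labels[[best[2]]] <- NULL
  }
  merges
}

test_that("clustering follows average linkage on 1 - rho distances", {
  rho <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.1,
                  0.1, 0.1, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cluster_tissues(structure(rho, class = c("correlation_matrix",
                                                 "matrix")))
  # first merge is the most correlated pair {A, B}
  expect_identical(sort(hc$labels[-hc$merge[1, ]]), c("A", "B"))
  expect_equal(hc$height[1], 0.1)

  # identical columns merge at height zero
  em <- make_matrix(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 1, 2)),
                    c(s1 = "a", s2 = "b", s3 = "c"))
  hc0 <- cluster_tissues(spearman_pairwise(em, level = "sample"))
  expect_equal(hc0$height[1], 0)

  # merge heights replay a naive hand agglomeration on a random 5-item matrix
  set.seed(14)
  vals <- matrix(stats::runif(60 * 5), 60, 5)
  em5 <- make_matrix(vals, stats::setNames(letters[1:5], paste0("s", 1:5)))
  rho5 <- spearman_pairwise(em5, level = "sample")
  hc5 <- cluster_tissues(rho5)
  d5 <- 1 - unclass(rho5)
  ref <- naive_average_linkage(d5)
  expect_equal(hc5$height, vapply(ref, `[[`, numeric(1), "height"))
  # and the clustering is label-permutation invariant up to relabeling
  perm <- c(4, 1, 5, 3, 2)
  hc5p <- cluster_tissues(structure(unclass(rho5)[perm, perm],
                                    class = c("correlation_matrix", "matrix")))
  expect_equal(hc5p$height, hc5$height)
  expect_identical(sort(hc5p$labels), sort(hc5$labels))
})

test_that("dendrograms serialize to Newick readable by ape", {
  em <- make_matrix(matrix(stats::runif(40 * 4), 40, 4),
                    c(s1 = "a", s2 = "b", s3 = "c", s4 = "d"))
  hc <- cluster_tissues(spearman_pairwise(em, level = "sample"))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, p)
  phy <- ape::read.tree(p)
  expect_setequal(phy$tip.label, c("s1", "s2", "s3", "s4"))
})

test_that("scatter pairs carry log2(x+1) coordinates and raw-scale Spearman", {
  em <- make_matrix(cbind(c(0, 1, 3), c(1, 3, 7)), c(s1 = "a", s2 = "b"))
  sp <- scatter_pair(em, "s1", "s2")
  expect_equal(sp$data$a, c(0, 1, 2))
  expect_equal(sp$data$b, c(1, 2, 3))
  expect_equal(sp$spearman, 1.0)
})
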