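test_that("average_by_tissue takes arithmetic means per tissue", {
  vals <- matrix(c(1, 3, 5, 0, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("h1", "h2", "k1")))
  em <- expression_matrix(vals, c(h1 = "heart", h2 = "heart", k1 = "kidney"))
  prof <- average_by_tissue(em)
  expect_equal(prof["g1", "heart"], 2.0)
  expect_equal(prof["g1", "kidney"], 5.0)   # single-sample tissue
  expect_equal(unname(prof["g2", ]), c(0, 0))  # all-zero gene
})

test_that("tissue-specific score follows the max-of-others convention", {
  expect_equal(tissue_specific_score(named_row(c(10, 2, 1, 1)), "t01"), 5.0)
  expect_equal(tissue_specific_score(named_row(c(0, 0, 0)), "t01"), 0)
  expect_identical(tissue_specific_score(named_row(c(3, 0, 0)), "t01"), Inf)
  expect_error(tissue_specific_score(named_row(c(1, 2)), "nope"),
               "unknown tissue")
})

test_that("group search matches its worked examples and the exhaustive oracle", {
  params <- classification_params()
  r1 <- row28(c(10, 10))
  expect_identical(sort(find_enriched_group(r1, params)), c("t01", "t02"))

  # k = 2 fails (9.5 < 5 x 8), k = 3 passes (9 >= 5 x 1)
  r2 <- row28(c(10, 9, 8))
  expect_identical(sort(find_enriched_group(r2, params)),
                   c("t01", "t02", "t03"))
  expect_true(oracle_group_exists(r2, params))

  # no group: top-2 mean 6.5 < 5 x 1.4, larger groups only lower the mean
  r3 <- row28(c(10, 3), fill = 1.4)
  expect_null(find_enriched_group(r3, params))
  expect_false(oracle_group_exists(r3, params))
})

test_that("top-k search agrees with exhaustive subset search on random panels", {
  set.seed(424242)
  for (trial in seq_len(300)) {
    n <- sample(5:12, 1)
    params <- classification_params(group_max = min(7L, n - 1L))
    v <- named_row(random_profile_vec(n))
    found <- find_enriched_group(v, params)
    expect_identical(!is.null(found), oracle_group_exists(v, params))
    if (!is.null(found)) {
      lev <- mean(v[found])
      expect_gte(lev, params$detection_cutoff)
      expect_gte(lev, params$fold_threshold * max(v[setdiff(names(v), found)]))
    }
  }
})

test_that("per-member group statistic is exposed and stricter than the mean", {
  pmin_ <- classification_params(group_statistic = "min")
  pmean <- classification_params()
  r <- row28(c(10, 9, 8))
  # mean rule admits {t01,t02,t03} (mean 9 >= 5); min rule needs 8 >= 5 too
  expect_identical(find_enriched_group(r, pmin_),
                   find_enriched_group(r, pmean))
  # mean (20 + 4.9)/2 = 12.45 clears 5 x 1, but the weakest member 4.9 does not
  r2 <- row28(c(20, 4.9), fill = 1)
  expect_identical(sort(find_enriched_group(r2, pmean)), c("t01", "t02"))
  expect_null(find_enriched_group(r2, pmin_))
  set.seed(99)
  for (trial in seq_len(100)) {
    n <- sample(5:12, 1)
    pm <- classification_params(group_max = min(7L, n - 1L),
                                group_statistic = "min")
    v <- named_row(random_profile_vec(n))
    expect_identical(!is.null(find_enriched_group(v, pm)),
                     oracle_group_exists(v, pm))
  }
})

test_that("classify_gene reproduces the six-category worked examples", {
  params <- classification_params()
  c1 <- classify_gene(row28(10), params)
  expect_identical(c1$category, "tissue_enriched")
  expect_identical(c1$elevated_tissues, "t01")

  c2 <- classify_gene(row28(numeric(), fill = 5), params)
  expect_identical(c2$category, "expressed_in_all")

  # panel mean 1.764: 10 >= 8.82 but 10 < 15, and no qualifying group
  r3 <- row28(c(10, 3), fill = 1.4)
  expect_equal(mean(r3), 49.4 / 28)
  c3 <- classify_gene(r3, params)
  expect_identical(c3$category, "tissue_enhanced")
  expect_identical(c3$elevated_tissues, "t01")

  c4 <- classify_gene(row28(numeric(), fill = 0.5), params)
  expect_identical(c4$category, "not_detected")

  c5 <- classify_gene(named_row(rep(c(2, 0.5), 14)), params)
  expect_identical(c5$category, "mixed")
})

test_that("enrichment ties at exactly five-fold count as passing", {
  r <- row28(5, fill = 1)  # 5 >= 5 x 1
  expect_identical(classify_gene(r)$category, "tissue_enriched")
})

test_that("every gene gets exactly one category and counts partition the panel", {
  set.seed(1234)
  vals <- matrix(10^stats::runif(200 * 10, -1, 2), 200, 10)
  prof <- make_profile(vals)
  params <- classification_params(group_max = 7L)
  cl <- classify_matrix(prof, params = params)
  expect_identical(nrow(cl), 200L)
  expect_true(all(cl$category %in% c("tissue_enriched", "group_enriched",
                                     "tissue_enhanced", "expressed_in_all",
                                     "mixed", "not_detected")))
  expect_identical(sum(category_counts(cl)), 200L)
  # elevated class <=> non-empty tissue set
  elev <- cl$category %in% c("tissue_enriched", "group_enriched",
                             "tissue_enhanced")
  expect_identical(nzchar(cl$elevated_tissues), elev)
  sizes <- lengths(strsplit(cl$elevated_tissues[elev], ";"))
  expect_true(all(sizes[cl$category[elev] == "tissue_enriched"] == 1L))
  grp <- sizes[cl$category[elev] == "group_enriched"]
  expect_true(all(grp >= params$group_min & grp <= params$group_max))
})

test_that("tissue_enriched coincides with score >= fold at the detected peak", {
  set.seed(77)
  params <- classification_params()
  for (trial in seq_len(200)) {
    v <- named_row(random_profile_vec(28))
    cl <- classify_gene(v, params)
    peak <- names(v)[which.max(v)]
    score <- tissue_specific_score(v, peak)
    rule <- v[[peak]] >= params$detection_cutoff &&
      score >= params$fold_threshold
    expect_identical(cl$category == "tissue_enriched", rule)
    if (cl$category == "tissue_enriched")
      expect_identical(cl$elevated_tissues, peak)
  }
})

test_that("classification is invariant to tissue relabeling and upscaling", {
  set.seed(31)
  params <- classification_params(group_max = 6L)
  for (trial in seq_len(50)) {
    v <- named_row(random_profile_vec(9))
    cl <- classify_gene(v, params)
    perm <- sample(length(v))
    clp <- classify_gene(v[perm], params)
    expect_identical(clp$category, cl$category)
    expect_identical(sort(clp$elevated_tissues), sort(cl$elevated_tissues))
    # fold rules are scale-free; only the absolute cutoff can change, and
    # upscaling never drops a gene out of an elevated category
    cls <- classify_gene(v * 7, params)
    if (cl$category %in% c("tissue_enriched", "group_enriched",
                           "tissue_enhanced")) {
      expect_identical(cls$category, cl$category)
      expect_identical(cls$elevated_tissues, cl$elevated_tissues)
    }
  }
})

test_that("classify_matrix composes per-gene calls and annotation flags", {
  rows <- rbind(row28(10),
                row28(c(10, 10)),
                row28(c(10, 3), fill = 1.4),
                row28(numeric(), fill = 5),
                row28(numeric(), fill = 0.5))
  prof <- make_profile(rows, genes = paste0("g", 1:5))
  ann <- data.frame(gene_id = paste0("g", 1:5),
                    gene_name = paste0("G", 1:5),
                    is_mitochondrial = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  cl <- classify_matrix(prof, ann)
  expect_identical(cl$category,
                   c("tissue_enriched", "group_enriched", "tissue_enhanced",
                     "expressed_in_all", "not_detected"))
  expect_true(cl$is_mitochondrial[4])
  expect_identical(cl$elevated_tissues[2], "t01;t02")
  expect_equal(cl$score_t01[1], 10)
  # genes missing from the annotation are warned about, not dropped
  expect_warning(classify_matrix(prof, ann[-1, ]), "missing from annotation")
  # empty profile classifies to an empty table
  empty <- make_profile(matrix(numeric(), 0, 28,
                               dimnames = list(NULL, colnames(prof))),
                        genes = character())
  expect_identical(nrow(classify_matrix(empty)), 0L)
})

test_that("elevated gene sets collect all three elevated classes per tissue", {
  rows <- rbind(row28(10), row28(10), row28(10),          # enriched in t01
                row28(c(10, 10)), row28(c(10, 10)),       # group {t01,t02}
                row28(c(10, 3), fill = 1.4),              # enhanced in t01
                row28(numeric(), fill = 5))               # expressed in all
  prof <- make_profile(rows, genes = paste0("g", 1:7))
  cl <- classify_matrix(prof)
  expect_setequal(elevated_genes(cl, "t01"), paste0("g", 1:6))
  expect_setequal(elevated_genes(cl, "t02"), c("g4", "g5"))
  expect_identical(elevated_genes(cl, "t05"), character())
  expect_error(elevated_genes(cl, "nope"), "unknown tissue")
})

test_that("tissue view partitions all genes and reports detection", {
  # 10 genes seen from t01: 2 not detected there, 3 elevated, 4 expressed
  # in all (1 mitochondrial), 1 detected but neither
  rows <- rbind(row28(numeric(), fill = 0.5),
                row28(c(0.2, 8), fill = 2),                # enriched in t02
                row28(10), row28(10), row28(c(10, 10)),
                row28(numeric(), fill = 5), row28(numeric(), fill = 5),
                row28(numeric(), fill = 5), row28(numeric(), fill = 5),
                named_row(rep(c(2, 0.5), 14)))
  prof <- make_profile(rows, genes = paste0("g", 1:10))
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    gene_name = paste0("g", 1:10),
                    is_mitochondrial = seq_len(10) == 6)
  cl <- classify_matrix(prof, ann)
  v <- tissue_view(cl, prof, "t01")
  expect_identical(unname(v$counts),
                   c(2L, 3L, 1L, 3L, 1L))
  expect_equal(v$detected_fraction, 0.8)
  expect_identical(sum(v$counts), 10L)

  all_eia <- make_profile(matrix(5, 4, 28,
                                 dimnames = list(paste0("h", 1:4),
                                                 colnames(prof))))
  cl2 <- classify_matrix(all_eia)
  expect_equal(tissue_view(cl2, all_eia, "t01")$detected_fraction, 1.0)

  set.seed(5)
  vals <- matrix(10^stats::runif(120 * 28, -1, 2), 120, 28)
  prof3 <- make_profile(vals)
  cl3 <- classify_matrix(prof3)
  v3 <- tissue_view(cl3, prof3, "t07")
  expect_identical(sum(v3$counts), 120L)
})
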