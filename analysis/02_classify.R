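#!/usr/bin/env Rscript
# Classify every gene into the six specificity categories and summarise the
# two striated muscles: elevated counts split by subcategory (the Table-1
# view) and the per-tissue pie-chart views.

library(tissuespec)

out <- "results"
em <- read_expression_matrix(file.path(out, "fpkm_matrix.tsv"),
                             file.path(out, "sample_map.tsv"))
ann <- read_gene_annotation(file.path(out, "gene_annotation.tsv"))
truth <- read_table(file.path(out, "ground_truth.tsv"))

prof <- average_by_tissue(em)
cl <- classify_matrix(prof, ann)
write_table(cl, file.path(out, "classification.tsv"))

counts <- category_counts(cl)
write_table(data.frame(category = names(counts), n = unname(counts)),
            file.path(out, "category_counts.tsv"))
cat("Category counts:\n"); print(counts)

truth$elevated_tissues[is.na(truth$elevated_tissues)] <- ""
cl_truth <- truth[match(cl$gene_id, truth$gene_id), ]
cat(sprintf("Planted-label recovery: %.2f%% (categories), %.2f%% (incl. tissue sets)\n",
            100 * mean(cl$category == cl_truth$category),
            100 * mean(cl$category == cl_truth$category &
                         cl$elevated_tissues == cl_truth$elevated_tissues)))

for (t in c("cardiac_muscle", "skeletal_muscle")) {
  ids <- elevated_genes(cl, t)
  cat3 <- table(cl$category[match(ids, cl$gene_id)])
  cat(sprintf("%s: %d elevated (%d enriched, %d group enriched, %d enhanced)\n",
              t, length(ids),
              cat3[["tissue_enriched"]], cat3[["group_enriched"]],
              cat3[["tissue_enhanced"]]))
}

views <- do.call(rbind, lapply(c("cardiac_muscle", "skeletal_muscle"),
  function(t) {
    v <- tissue_view(cl, prof, t)
    cat(sprintf("%s: %.1f%% of genes detected (FPKM >= 1)\n",
                t, 100 * v$detected_fraction))
    data.frame(tissue = t, slice = names(v$counts), n = unname(v$counts),
               detected_fraction = v$detected_fraction)
  }))
write_table(views, file.path(out, "tissue_views.tsv"))
cat("Wrote classification.tsv, category_counts.tsv, tissue_views.tsv\n")
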