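#!/usr/bin/env Rscript
# mRNA pool composition of the two striated muscles: what share of each
# tissue's transcript mass comes from mitochondrial housekeeping genes,
# other housekeeping genes, and genes elevated in that tissue; plus the
# most abundant genes per muscle.

library(tissuespec)

out <- "results"
em <- read_expression_matrix(file.path(out, "fpkm_matrix.tsv"),
                             file.path(out, "sample_map.tsv"))
ann <- read_gene_annotation(file.path(out, "gene_annotation.tsv"))
prof <- average_by_tissue(em)
cl <- classify_matrix(prof, ann)

muscles <- c("cardiac_muscle", "skeletal_muscle")
comp <- do.call(rbind, lapply(muscles, function(t) {
  pc <- pool_composition(prof, cl, t)
  print(pc)
  as.data.frame(pc)
}))
write_table(comp, file.path(out, "pool_composition.tsv"))

top <- do.call(rbind, lapply(muscles, function(t) {
  ta <- top_abundant(prof, t, 20L)
  cat(sprintf("%s lead transcript: %s at FPKM %.0f\n",
              t, ta$gene_id[1], ta$fpkm[1]))
  cbind(tissue = t, ta)
}))
write_table(top, file.path(out, "top_abundant.tsv"))
cat("Wrote pool_composition.tsv, top_abundant.tsv\n")
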