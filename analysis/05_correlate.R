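#!/usr/bin/env Rscript
# Global expression-profile similarity: pairwise Spearman correlations
# between samples and between tissue averages, and an average-linkage
# dendrogram of the tissues on distance 1 - rho.

library(tissuespec)

out <- "results"
em <- read_expression_matrix(file.path(out, "fpkm_matrix.tsv"),
                             file.path(out, "sample_map.tsv"))

rho_s <- spearman_pairwise(em, level = "sample")
pair <- function(t) names(em$sample_tissue)[em$sample_tissue == t][1:2]
hp <- pair("cardiac_muscle"); sp <- pair("skeletal_muscle")
cat(sprintf("Same-tissue replicate Spearman: cardiac %.3f, skeletal %.3f\n",
            rho_s[hp[1], hp[2]], rho_s[sp[1], sp[2]]))

rho_t <- spearman_pairwise(em, level = "tissue")
cat(sprintf("Cardiac vs skeletal muscle (tissue averages): rho = %.3f\n",
            rho_t["cardiac_muscle", "skeletal_muscle"]))
write_table(data.frame(tissue = rownames(rho_t),
                       as.data.frame(unclass(rho_t)), check.names = FALSE),
            file.path(out, "tissue_spearman.tsv"))

hc <- cluster_tissues(rho_t)
write_newick(hc, file.path(out, "tissue_dendrogram.nwk"))

sc <- scatter_pair(em, hp[1], hp[2])
write_table(sc$data, file.path(out, "scatter_cardiac_pair.tsv"))
cat("Wrote tissue_spearman.tsv, tissue_dendrogram.nwk,",
    "scatter_cardiac_pair.tsv\n")
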