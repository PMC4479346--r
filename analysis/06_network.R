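#!/usr/bin/env Rscript
# Enrichment-combination network around the two striated muscles: one node
# per distinct enriched tissue combination (size = sqrt of its gene count),
# connected to the member tissues; plus the genes enriched in both muscles.

library(tissuespec)

out <- "results"
em <- read_expression_matrix(file.path(out, "fpkm_matrix.tsv"),
                             file.path(out, "sample_map.tsv"))
ann <- read_gene_annotation(file.path(out, "gene_annotation.tsv"))
cl <- classify_matrix(average_by_tissue(em), ann)

focus <- c("cardiac_muscle", "skeletal_muscle")
net <- build_network(cl, focus)
write_network(net, file.path(out, "enrichment_network.graphml"),
              file.path(out, "enrichment_edges.tsv"))
nodes <- network_nodes(net)
cat(sprintf("Network: %d combination nodes over %d genes, %d edges\n",
            nrow(nodes), sum(nodes$count), igraph::ecount(net)))
cat("Largest combinations:\n")
print(utils::head(nodes[order(-nodes$count), ], 5), row.names = FALSE)

shared <- shared_enriched(cl, "cardiac_muscle", "skeletal_muscle")
cat(sprintf("Genes enriched in both muscles: %d\n", length(shared)))
writeLines(shared, file.path(out, "shared_enriched_genes.txt"))
cat("Wrote enrichment_network.graphml, enrichment_edges.tsv,",
    "shared_enriched_genes.txt\n")
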