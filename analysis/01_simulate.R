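#!/usr/bin/env Rscript
# Generate the synthetic 28-tissue FPKM panel used by the downstream
# analysis scripts. The sample layout mirrors the study design: 4 cardiac
# muscle samples (2 "auricle" + 2 "ventricle" in script 04), 5 skeletal
# muscle samples, 3 samples for every other tissue.

library(tissuespec)

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spt <- simulation_config(seed = 101L)$samples_per_tissue
spt[["cardiac_muscle"]] <- 4L
spt[["skeletal_muscle"]] <- 5L

cfg <- simulation_config(samples_per_tissue = spt, seed = 101L)
pr <- generate_profile(cfg)
em <- scatter_samples(pr$profile, cfg)

write_expression_matrix(em, file.path(out, "fpkm_matrix.tsv"),
                        file.path(out, "sample_map.tsv"))
write_table(pr$truth, file.path(out, "ground_truth.tsv"))
write_table(truth_annotation(pr$truth), file.path(out, "gene_annotation.tsv"))

cat(sprintf("Simulated %d genes x %d samples (%d tissues), seed %d\n",
            nrow(em$values), ncol(em$values),
            length(unique(em$sample_tissue)), cfg$seed))
cat(sprintf("Planted categories: %s\n",
            paste(names(cfg$planted_counts), cfg$planted_counts,
                  sep = "=", collapse = ", ")))
cat("Wrote fpkm_matrix.tsv, sample_map.tsv, gene_annotation.tsv,",
    "ground_truth.tsv under results/\n")
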