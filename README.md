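# tissuespec

Classification of tissue-specific gene expression from multi-tissue FPKM
panels, in R.

Given a gene × sample matrix of FPKM values across a panel of tissues (the
design behind body-wide RNA-seq atlases such as the 28-tissue human panel
with cardiac and skeletal muscle), the package answers: which genes are
specific to which tissues, what does each tissue's mRNA pool consist of,
which genes differ between regions of an organ, how similar are the
tissues globally, and which tissue combinations share enriched genes?

## The classification scheme

Samples are averaged within tissues, and each gene's per-tissue FPKM
vector x = (x₁, …, xₙ) is assigned exactly one of six categories
(cutoff = 1 FPKM, fold = 5 by default, evaluated in this order):

| category | rule |
|---|---|
| tissue enriched | ∃t: xₜ ≥ cutoff and xₜ ≥ fold · max(x₋ₜ) |
| group enriched | a group G of 2–7 tissues with mean(x_G) ≥ fold · max(x outside G), mean(x_G) ≥ cutoff |
| tissue enhanced | ∃t: xₜ ≥ cutoff and xₜ ≥ fold · mean(x) |
| expressed in all | xₜ ≥ cutoff for every tissue ("housekeeping") |
| not detected | xₜ < cutoff for every tissue |
| mixed | detected somewhere, no elevation, not everywhere |

The first three classes together are a tissue's *elevated* genes. The
tissue-specific score of tissue t is xₜ / max(x₋ₜ). The group search
scans only the top-k tissues per size k — provably equivalent to
exhaustive subset search, which the tests verify by enumeration.

On top of the classifier: mRNA pool composition (share of a tissue's
FPKM mass per gene class, with a mitochondrial housekeeping slice),
five-fold mean-FPKM differential expression between sample groups,
pairwise Spearman correlation with average-linkage clustering (Newick
export), and a bipartite network of enriched tissue combinations
(GraphML export). A synthetic-data generator plants genes of every
category with known ground truth so the full pipeline is testable
offline; see the methods vignette
(`vignettes/tissue-specificity-methods.Rmd`) for design details.

## Worked example

```r
library(tissuespec)

cfg <- simulation_config(seed = 42L)       # 28 tissues x 3 samples, 5000 genes
pr  <- generate_profile(cfg)               # tissue means + ground truth
em  <- scatter_samples(pr$profile, cfg)    # per-sample FPKM with log-normal noise

prof <- average_by_tissue(em)
cl   <- classify_matrix(prof, truth_annotation(pr$truth))

category_counts(cl)
#>  tissue_enriched   group_enriched  tissue_enhanced expressed_in_all
#>              401              400              399             2050
#>            mixed     not_detected
#>             1000              750

recovery_rate(cl, pr$truth)
#> [1] 0.9998

pool_composition(prof, cl, "cardiac_muscle")
#> <pool_composition> cardiac_muscle
#>   mitochondrial                  29.8%  (150 genes)
#>   expressed_in_all_other         25.3%  (1900 genes)
#>   elevated_in_tissue             27.2%  (107 genes)
#>   other                          17.7%  (2843 genes)

rho <- spearman_pairwise(em, level = "sample")
rho["cardiac_muscle_s1", "cardiac_muscle_s2"]
#> [1] 0.9802124
```

The classifier recovers 99.98% of the planted categories under default
noise (two mixed genes drift over a threshold) and 100% on the noiseless
profile; the mitochondrial block carries ~30% of the cardiac mRNA pool by
construction, and replicate samples correlate at ρ ≈ 0.98, the regime
reported for real same-tissue RNA-seq replicates.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `06_network.R`), each writing its tables under
`results/`; run them in order from the repository root.

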