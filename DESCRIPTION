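Package: tissuespec
Title: Tissue-Specificity Classification of Gene Expression from FPKM Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies protein-coding genes into six tissue-specificity
    categories (tissue enriched, group enriched, tissue enhanced, expressed
    in all, mixed, not detected) across a multi-tissue panel of FPKM
    expression matrices, using threshold and fold-change rules. Computes
    tissue-specific scores, per-tissue mRNA pool composition, five-fold
    mean-FPKM differential expression between sample groups, pairwise
    Spearman correlation with average-linkage clustering, and a bipartite
    network of tissue-combination enrichment. Includes a synthetic-data
    generator that plants genes of each category with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
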