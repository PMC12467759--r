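Package: dicoex
Title: Differential Expression and Co-Expression Analysis of IDH-Status Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-cohort transcriptomic analysis workflow contrasting IDH-mutant
    and IDH wild-type lower-grade glioma samples: rank-based differential
    expression (Wilcoxon rank-sum with Bonferroni/Benjamini-Hochberg correction),
    differential co-expression of gene pairs via Fisher-transformed Pearson
    correlations, cross-dataset replication with direction-consistency rules,
    integration of the two gene lists, hypergeometric gene-set
    over-representation, Markov clustering of the integrated genes on a
    protein-protein interaction network, cross-platform L1-penalised
    classification of mutation status, and export of ranked up/down gene
    signatures. A seedable two-platform synthetic-data generator with planted
    differential expression and co-expression supports end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
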