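Package: netmarker
Title: Network-Driven Prognostic Biomarker Discovery from Protein
    Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for discovering prognostic gene-expression
    biomarkers from protein-protein interaction networks, developed around
    post-myocardial-infarction outcome prediction from blood transcriptomes.
    Reads interaction networks (edge list or SIF), extracts the giant
    component, ranks high-traffic bottleneck proteins by betweenness
    centrality, detects modules by greedy modularity maximization, tests
    module annotation enrichment (GO / miRNA target sets in GMT format)
    with two-tailed Fisher exact tests and Benjamini-Hochberg correction,
    scores genes and module mean-expression profiles for differential
    expression between outcome classes (Mann-Whitney), normalizes qPCR Ct
    tables against a housekeeping gene, and evaluates candidate biomarker
    panels with ridge-penalized logistic regression under leave-one-out
    cross-validation summarized by AUC. Seeded synthetic-data generators
    (planted-partition networks, two-class expression matrices, annotation
    collections, Ct tables) make every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    pROC,
    glmnet
Config/testthat/edition: 3
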