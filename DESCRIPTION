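Package: enrichmapr
Title: Enrichment-Map Pathway Networks from Two-Class RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline from a two-class RNA-Seq count matrix (or a
    pre-ranked gene list) and a GMT gene-set database to a clustered
    enrichment-map network. Counts are filtered with the filterByExpr rule,
    normalized with trimmed-mean-of-M-values (TMM) factors, and tested for
    differential expression with the conditional negative-binomial exact test
    under a common quantile-adjusted dispersion. Genes are ranked by signed
    -log10 p-value and scored against gene sets with preranked gene-set
    enrichment analysis (weighted running-sum enrichment scores, a
    gene-sampling permutation null, normalized enrichment scores and
    Benjamini-Hochberg q-values). Significant sets become nodes of a network
    whose edges link sets with high Jaccard member overlap; connected
    components (or greedy modularity communities) define clusters, each given
    a word-frequency label. Includes a negative-binomial simulator with
    planted differential expression and planted gene-set structure, readers
    and writers for GMT, RNK, expression tables, result tables and network
    files, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
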