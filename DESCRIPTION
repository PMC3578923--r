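Package: pathosim
Title: Pathophenotypic Similarity Gene Networks from Ontology Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-gene semantic similarity networks from ontology
    annotations of disease-causing genes (Resnik information content, best-match
    average similarity), projects bipartite disease-gene tables onto unipartite
    disease-causing gene networks, classifies genes by disease genicity and gene
    tropy, compares networks by edge intersection with hypergeometric
    significance against degree-preserving randomizations, runs resampled
    Mann-Whitney topology tests and ROC validation of similarity scores against
    biomolecular interactomes, and extracts disease modules around seed genes.
    Includes a synthetic-data generator (ontologies, diseasomes, annotations,
    interactomes with planted overlap) so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
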