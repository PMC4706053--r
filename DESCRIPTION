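Package: hetnetr
Title: Heterogeneous Biological Networks for Complex Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, filters and analyses heterogeneous biological networks
    (hetnets) that integrate phenotypes, genes, miRNAs, tissues, drugs and
    drug side effects under a typed metagraph. Provides an OBO ontology
    reader with rooting and downward annotation propagation (ontology
    inference of phenotype-tissue and side-effect-tissue links), gene-alias
    and phenotype cross-vocabulary identifier resolution, resource-table
    ingestion with evidence and p-value filters and GWAS locus merging,
    seed-and-expand network construction, bipartite-to-homogeneous similarity
    projection, topology reporting, SIF/GraphML interchange, a command-line
    interface, and a seeded synthetic-resource generator with brute-force
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
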