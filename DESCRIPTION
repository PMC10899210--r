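Package: dgnet
Title: Disease Gene Networks from Protein Interactomes and Developmental
    Brain Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease interactomes from seed genes and protein-protein
    interaction edge tables, quantifies interactome overlap with log-space
    hypergeometric tests, clusters interactome genes by spatiotemporal brain
    expression (Pearson-correlation distance, UPGMA) into disease gene
    networks (DGNs), characterises DGNs by SVD-imputation PCA quadrants and
    hypergeometric over-representation with Benjamini-Hochberg control,
    co-clusters enrichment profiles via rank-based inverse-normal z-scores,
    and detects densely interconnected topological modules by k-core vertex
    weighting and seed expansion. Includes a synthetic-data generator with
    planted temporal archetypes and controlled interactome overlap so the
    whole pipeline is testable without database downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
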