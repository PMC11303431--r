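Package: coexrank
Title: Weighted Co-Expression Modules, Eigengene-Trait Association and
    Dual Pearson/MIC Candidate Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for nominating candidate regulators from bulk
    transcriptomes with quantitative histological traits: weighted co-expression
    network construction (soft-thresholded adjacency, topological overlap),
    module detection by average-linkage clustering of TOM dissimilarity, module
    eigengenes and their correlation with traits, hub-gene ranking by gene
    significance and intramodular centrality, dual ranking of omics features
    against a trait by Pearson correlation and the maximal information
    coefficient (implemented from the published MINE grid search) with top-k
    intersection and gene-set annotation, and one-sided hypergeometric
    set-overlap tests. Includes a synthetic-cohort generator with planted
    modules, trait links and nonlinear peptide responses so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
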