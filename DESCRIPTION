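Package: entronet
Title: Enterotyping and Clinical-Microbial Network Analysis for 16S Gut
    Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-group 16S rRNA gut microbiome
    cohort studies: feature-table filtering, rarefaction and rank
    aggregation; alpha/beta diversity with Wilcoxon and PERMANOVA group
    tests; per-taxon Wilcoxon screening and a two-class LEfSe-style LDA
    effect-size procedure; Jensen-Shannon/PAM enterotyping with
    Calinski-Harabasz model selection and between-class analysis; a
    clinical statistics battery (chi-square, Fisher, rank-sum, pooled
    two-proportion z, propensity matching); and clinical-microbial
    Spearman correlation networks with betweenness and HITS hub/authority
    centrality. Includes a Dirichlet-multinomial synthetic-data generator
    with Gaussian-copula association planting so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    igraph,
    MASS,
    picante,
    phyloseq,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
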