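Package: holonet
Title: Cross-Compartment Expression Networks and Symbiosis Dynamics for
    Coral Meta-Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for tri-compartment (coral host,
    Symbiodiniaceae, prokaryote) transcriptomic experiments under nutrient
    enrichment. Provides negative-binomial count simulation with planted
    differential expression, cross-compartment correlation structure and
    physiology drivers; pairwise differential-expression calling with
    fold-change and p-value thresholds, Venn partitioning and ordination
    transforms; bipartite Spearman co-expression networks with size-adjusted
    betweenness centrality and core-transcript extraction; a repeated
    random-subset L1-penalized linear mixed-model procedure linking
    transcripts to symbiont physiology; and a tripartite Lotka-Volterra
    symbiosis model with equilibrium, isocline, and regime analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
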