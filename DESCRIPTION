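Package: aflpop
Title: Dominant-Marker Population Genetics of Clonal, Self-Incompatible Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dominant (AFLP-style) presence/absence
    marker data from clonal, self-incompatible plant invasions. Estimates
    replicate-based genotyping error rates and calls clonal lineages by the
    error-rate threshold rule; computes per-group fragment classes and Nei's
    gene diversity; runs principal coordinates analysis on Nei & Li (Dice)
    distances with rank tests on axes; performs hierarchical analysis of
    molecular variance (AMOVA) with phi-statistics and permutation tests;
    infers self-incompatibility crossing groups and mate availability from
    crossing records; summarises reproductive traits (androecium mutants,
    pollen, ovules, seeds) and their Spearman correlations with genetic
    diversity, including Mantel-style genetic-geographic distance tests.
    Includes a forward simulator of self-incompatible clonal colonization
    with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
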