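Package: genecoev
Title: Correlated Gene Loss, Evolutionary Rate Covariation, and
    Interactome Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests for correlated, irreversible gene loss on a
    time-calibrated phylogeny by comparing nested continuous-time Markov
    models (independent versus dependent loss rates) with a likelihood
    ratio test; computes evolutionary rate covariation (ERC) between
    genes from branch-specific relative rates, with pathway-mean
    statistics and a permutation null; and calls enriched protein
    interactors from BioID and co-immunoprecipitation spectral-count
    tables using peptide and fold-enrichment filters with isoform
    collapsing. Includes seeded simulators for pure-birth trees, paired
    loss traits, correlated branch rates and spectral counts, so every
    stage of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
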