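Package: resubr
Title: Two-Epoch Reduced-Alphabet Amino Acid Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phylogenetic inference under refinement-expansion
    substitution ("resub") models, in which the amino acid coding alphabet
    changes size at an estimated epoch boundary. Provides reduced-alphabet
    basis construction, saltation matrices, epoch-aware Felsenstein pruning
    likelihoods on dated trees, forward simulation of birth-death time-trees
    and two-epoch alignments, Bayesian Markov chain Monte Carlo inference
    with model averaging over the four alphabet hypotheses, convergence
    diagnostics, and simulation-study harnesses (coverage, model recovery,
    and divergence-age bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    coda,
    jsonlite
Config/testthat/edition: 3
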