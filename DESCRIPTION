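Package: collemsel
Title: Mitochondrial Selection Signatures and Life-Form Evolution in Springtails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking mitochondrial protein-coding gene
    selection signatures to the evolution of ecological life forms on a dated
    phylogeny, built around the Collembola (springtail) mitogenome analysis
    workflow. Provides ancestral discrete-trait reconstruction (Fitch/Hartigan
    parsimony, Mk1 and asymmetric Mk maximum likelihood with likelihood-ratio
    tests, and Bayesian MCMC with support calls), retention-index homoplasy
    scores, Nei-Gojobori-style synonymous/nonsynonymous site and pathway
    counting on reconstructed ancestral codon sequences under the invertebrate
    mitochondrial genetic code, Goldman-Yang (GY94) codon site models (M0,
    M1a, M2a) with likelihood-ratio tests and empirical-Bayes site posteriors,
    shift-versus-sister clade comparisons with paired t tests and
    proportion-versus-age regressions, TreeSAAP-style radical physicochemical
    amino-acid property change detection with sliding windows, and a
    simulator (birth-death trees, Mk traits, Gillespie GY94 codon evolution)
    so every stage is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
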