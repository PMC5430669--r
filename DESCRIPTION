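Package: gilliflow
Title: Coalescent Demographic Inference for Two Diverged Frog Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rejection-sampling approximate-likelihood inference of
    two-population demographic models (isolation, ongoing migration,
    secondary contact) from multi-locus phased exon sequences, using the
    four Wakeley-Hey polymorphism summary statistics at synonymous sites.
    Includes a structured-coalescent simulator with infinite-sites
    mutation and per-locus rate scalars, boundary-corrected chi-square
    mixture tests for nested model comparison, profile-likelihood
    confidence intervals, per-population nucleotide diversity with
    length-weighted bootstrap confidence intervals, rarefied allelic
    richness, pairwise FST with permutation tests, and a synthetic-data
    generator that emulates a multi-locus phased Sanger study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
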