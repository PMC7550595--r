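Package: matearray
Title: Mating System and Population Structure from Open-Pollinated Progeny Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of codominant microsatellite (SSR) genotypes of
    open-pollinated families (mother trees and their seed progeny) sampled
    across multiple populations. Implements the mixed-mating model with
    correlated paternity estimated by expectation-maximization (multilocus and
    single-locus outcrossing rates, maternal inbreeding, correlations of
    paternity and of selfing) with bootstrap standard errors over progeny
    arrays; Micro-Checker-style screening for null alleles, stuttering and
    large-allele dropout with null-allele frequency estimation; allele
    frequencies, heterozygosities, single- and multilocus F_st with chi-square
    tests, pairwise F_st, isolation-by-distance regression of F_st/(1-F_st) on
    log geographic distance with Mantel permutation tests, and altitude
    correlations; island-model gene-flow helpers; and a synthetic
    progeny-array generator (mixed mating, correlated paternity, genotyping
    errors, spatial structure) so every stage is verifiable by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
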