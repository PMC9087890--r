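Package: imcoal
Title: Two-Deme Isolation-Migration Inference from the Joint Site Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent-simulation based demographic inference for a pair of
    diverged lineages, in the style of SFS composite-likelihood tools used in
    phylogeography. Defines ten variants of the two-population
    isolation-migration model (isolation only, continuous, ancient-only and
    recent-only gene flow, symmetric and unidirectional), approximates the
    expected joint site frequency spectrum by structured-coalescent simulation,
    fits models to an observed spectrum by multinomial composite likelihood
    with an ECM-style cyclic optimizer, ranks models by AIC and Akaike weights,
    and attaches parametric-bootstrap confidence intervals to the best fit.
    Also provides the supporting population-genetic statistics (observed and
    unbiased expected heterozygosity, per-SNP nucleotide diversity,
    hierarchical AMOVA with permutation tests, Mantel tests, great-circle
    distances) and a ddRAD-like synthetic data generator producing VCF,
    population maps and coordinate/environment tables with two diverged
    lineages plus optional admixed populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    geosphere,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
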