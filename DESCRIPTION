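Package: coalfit
Title: Posterior Predictive Neutrality Tests for Multilocus Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether multilocus patterns of nucleotide diversity,
    population differentiation (Phi-ST) and the allele-frequency spectrum
    (Tajima's D) are consistent with neutral coalescent models of population
    history. Provides a structured-coalescent simulator with migration,
    exponential growth, demographic events and intra-locus recombination
    under the infinite-sites model; builders for two-island,
    isolation-with-migration, pre-divergence bottleneck and three-population
    hybridization demographies; machinery to assemble simulation histories
    from posterior-sample tables with locus-specific relative substitution
    rates, recombination rates and fragment lengths; posterior predictive
    goodness-of-fit tests at the dataset and locus level with false
    discovery rate control; and a multilocus Hudson-Kreitman-Aguade
    neutrality test with iterative outlier removal and cross-outgroup
    consensus calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
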