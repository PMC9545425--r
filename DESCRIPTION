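Package: radabc
Title: SNP Quality Control, Population-Genetic Statistics, and ABC Random-Forest
    Demographic Inference for RAD-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for population-genomic analysis of reduced-representation
    (RAD-seq) SNP genotypes: a reproducible variant and sample quality-control
    chain (call rate, minor-allele count, indels, Hardy-Weinberg exact tests,
    linkage-disequilibrium pruning, missingness, PI-HAT relatedness); diversity
    and differentiation statistics (nucleotide diversity, heterozygosity and
    inbreeding coefficients, Tajima's D, Weir-Cockerham F_ST with bootstrap
    confidence intervals and permutation tests, Nei distances with
    neighbour-joining trees, Patterson-scaled PCA); and demographic inference by
    approximate Bayesian computation with random forests (ABC-RF), driven by a
    built-in coalescent simulator of user-defined divergence/admixture scenarios
    that doubles as a synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
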