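Package: replifst
Title: Population Differentiation and the Replicability of Genetic Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links inter-population genetic differentiation (FST) of
    disease-associated genes to the replicability of candidate-gene
    association studies. Implements the Weir-Cockerham variance-components
    FST estimator on allele counts, gene-level FST aggregation (mean, max,
    tagSNP mean), greedy tagSNP selection by pairwise r-squared, ancestral
    versus derived allele classification by outgroup parsimony, Cramer's phi
    as a discordance index of continental replicability, a gene-resampling
    null for set-level FST, derived-allele contingency tests, and forward
    stepwise regression with standardized coefficients. A synthetic-data
    generator (Balding-Nichols allele frequencies, binomial genotypes, a
    power/false-positive model for study outcomes) provides ground-truth
    data for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
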