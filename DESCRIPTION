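Package: regrowqtl
Title: Mapping Dominant Complementary Regrowth Loci in Maize-Teosinte F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic analysis of the binary regrowth (perennialism) trait in
    Zea diploperennis x Zea mays F2 intercross populations. Implements
    chi-square goodness-of-fit machinery for k-locus dominant complementary
    segregation models (3:1, 9:7, 27:37), a four-stage SNP filtration cascade
    for genotyping-by-sequencing marker matrices (site coverage and minor
    allele frequency, missingness removal with heterozygote imputation, a
    9:7-model-constrained contingency chi-square filter, and 100-bp
    same-haplotype cluster collapsing), and a binary-trait single-locus
    genome scan: hidden Markov model conditional genotype probabilities with
    a genotyping-error allowance, EM estimation of genotype-specific
    penetrances, LOD profiles, genome-wide permutation thresholds, and
    significant-interval calling. A seeded F2/backcross simulator with a
    GBS-like noise model makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
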