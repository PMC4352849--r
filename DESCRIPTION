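Package: strpop
Title: Forensic STR Population Genetics: Summary Statistics, Exact Tests,
    Differentiation, Trees and PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for autosomal short tandem repeat
    (STR) population studies in forensic genetics. Computes per-locus forensic
    parameters (observed and expected heterozygosity, polymorphism information
    content, power of discrimination, probability of exclusion, typical
    paternity index) and their cumulative combinations; exact tests of
    Hardy-Weinberg equilibrium by complete enumeration or a Guo-Thompson
    Markov chain; genotypic linkage-disequilibrium permutation tests with
    Bonferroni correction and a locus-exclusion rule; Weir-Cockerham
    pairwise and overall Fst with permutation p-values; Nei's DA genetic
    distance; UPGMA and neighbor-joining trees with bootstrap-over-loci
    support values; and PCA of population allele frequencies. Includes a
    Balding-Nichols multi-population genotype simulator with controllable
    differentiation, inbreeding and linkage disequilibrium, plus readers and
    writers for genotype CSV, allele-frequency CSV and GenePop formats with a
    documented microvariant allele convention.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
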