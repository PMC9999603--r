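Package: kinlink
Title: Relationship Inference from Low-Coverage Sequencing Reads with Linked Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-ratio computations for hypotheses about pedigrees
    relating two or more tested persons, using raw A/C/G/T read counts from
    low-coverage next-generation sequencing (lcNGS) instead of called
    genotypes. Implements a read-count observational model with allelic
    drop-out and drop-in, an Fst-adjusted Dirichlet-multinomial founder
    allele model, and a Lander-Green hidden Markov model over linked SNPs
    whose inheritance-vector state space is compressed by the group of
    IBD-preserving hypercube isometries. Includes a gene-dropping simulator
    for whole-panel synthetic cases and tools to compare the full method
    against genotype-calling and linkage-ignoring variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
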