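Package: hemiphase
Title: Pedigree-Based Phasing and Clonality Analysis for Hybridogenetic
    Water-Frog Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing experimental crosses in hemiclonal
    (hybridogenetic) systems such as the Pelophylax esculentus complex.
    Assigns taxa (RR/RL/LL) from species-diagnostic microsatellite or SNP
    alleles, phases each backcross offspring's diploid genotype into a
    recombinant maternal haplotype and a clonal paternal haplotype using
    family segregation patterns, screens null-allele artifacts, clusters
    phased multilocus genotypes with missing-data tolerance, classifies
    each hybrid father's gamete production ([L], [R], or amphispermic),
    flags genome-leakage events, and contrasts clonal against recombining
    transmission with two-point recombination fractions. A seeded cross
    simulator with full ground truth emulates the crossing design so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
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
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
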