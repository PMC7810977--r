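# Small in-code fixtures shared across test files.

# Two-locus registry: one L-specific, one R-specific allele at "A";
# "B" R-diagnostic only with a shared pool implied by use.
toy_registry <- function() {
  locus_registry(c("A", "B"),
                 l_alleles = list("101", character()),
                 r_alleles = list("103", c("152", "154")))
}

# Build a genotype table from compact per-individual genotype strings:
# list(ind = c(A = "101/103", B = "152/152", C = NA, D = "140/-")).
make_genotypes <- function(calls, registry, ...) {
  rows <- purrr::imap_dfr(calls, function(loci, ind) {
    purrr::imap_dfr(loci, function(gt, loc) {
      a <- if (is.na(gt)) c(NA, NA) else strsplit(gt, "/", fixed = TRUE)[[1]]
      tibble::tibble(individual = ind, locus = loc,
                     allele_1 = a[1], allele_2 = a[2])
    })
  })
  genotype_table(rows, registry, ...)
}

# One-cross pedigree.
make_pedigree <- function(offspring, mother = "MOM", father = "DAD",
                          cross_id = "C1", sex = "undetermined") {
  tibble::tibble(cross_id = cross_id, mother_id = mother, father_id = father,
                 offspring_id = offspring,
                 sex = rep_len(sex, length(offspring)))
}

# A clean hybrid trio family over the published loci: father's [L] haplotype
# is transmitted clonally to `n_sons` RL sons.
clean_hybrid_family <- function(n_sons = 4, registry = waterfrog_loci()) {
  fL <- c(RICA2a34 = "144", RICA5 = "262", Rrid013A = "301", Ga1a19 = "197",
          RICA18 = "188", RICA1b5 = "120", Res14 = "140", Res20 = "124",
          Re1Caga10 = "95", Re2Caga3 = "165", RICA1b6 = "70", Res22 = "79",
          Rrid059A = "125", Rrid082A = "158", Rrid169A = "180")
  fR <- c(RICA2a34 = "150", RICA5 = "250", Rrid013A = "287", Ga1a19 = "203",
          RICA18 = "180", RICA1b5 = "134", Res14 = "146", Res20 = "118",
          Re1Caga10 = "110", Re2Caga3 = "173", RICA1b6 = "77", Res22 = "85",
          Rrid059A = "129", Rrid082A = "163", Rrid169A = "187")
  m1 <- c(RICA2a34 = "150", RICA5 = "250", Rrid013A = "287", Ga1a19 = "207",
          RICA18 = "180", RICA1b5 = "136", Res14 = "146", Res20 = "118",
          Re1Caga10 = "106", Re2Caga3 = "204", RICA1b6 = "80", Res22 = "106",
          Rrid059A = "131", Rrid082A = "169", Rrid169A = "189")
  m2 <- c(RICA2a34 = "152", RICA5 = "256", Rrid013A = "293", Ga1a19 = "211",
          RICA18 = "184", RICA1b5 = "140", Res14 = "150", Res20 = "122",
          Re1Caga10 = "108", Re2Caga3 = "212", RICA1b6 = "83", Res22 = "113",
          Rrid059A = "135", Rrid082A = "178", Rrid169A = "192")
  loci <- registry$locus
  sons <- sprintf("SON%02d", seq_len(n_sons))
  rows <- dplyr::bind_rows(
    tibble::tibble(individual = "DAD", locus = loci,
                   allele_1 = unname(fL[loci]), allele_2 = unname(fR[loci])),
    tibble::tibble(individual = "MOM", locus = loci,
                   allele_1 = unname(m1[loci]), allele_2 = unname(m2[loci])),
    purrr::imap_dfr(sons, function(s, i) {
      mat <- ifelse((seq_along(loci) + i) %% 2 == 0, m1[loci], m2[loci])
      tibble::tibble(individual = s, locus = loci,
                     allele_1 = unname(mat), allele_2 = unname(fL[loci]))
    }))
  list(genotypes = genotype_table(rows, registry),
       pedigree = make_pedigree(sons, sex = "male"),
       registry = registry, father_L = fL, father_R = fR,
       mother = list(m1 = m1, m2 = m2))
}

# High-diversity registry for linkage tests: every maternal genotype is
# almost surely heterozygous.
diverse_registry <- function(n_loci = 4, n_alleles = 16) {
  pools <- lapply(seq_len(n_loci), function(i) {
    as.character(seq(100 + 40 * i, by = 2, length.out = n_alleles))
  })
  locus_registry(paste0("U", seq_len(n_loci)),
                 lapply(seq_len(n_loci), function(i) character()),
                 pools)
}
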