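# The phasing engine: locus filtering, null screening, per-offspring and
# family-level phasing.

test_that("locus filter applies the parent and offspring-presence rules", {
  fam <- clean_hybrid_family(n_sons = 10)
  g <- fam$genotypes
  # blank one locus in 3/10 sons (70% presence) and another in the father
  g$allele_1[g$individual %in% c("SON01", "SON02", "SON03") &
               g$locus == "Res22"] <- NA
  g$allele_2[g$individual %in% c("SON01", "SON02", "SON03") &
               g$locus == "Res22"] <- NA
  g$allele_1[g$individual == "DAD" & g$locus == "Ga1a19"] <- NA
  g$allele_2[g$individual == "DAD" & g$locus == "Ga1a19"] <- NA
  filt <- filter_family_loci("C1", fam$pedigree, g, fam$registry,
                             offspring_presence = 0.75)
  expect_false(filt$retained[filt$locus == "Res22"])
  expect_equal(filt$reason[filt$locus == "Res22"], "offspring_presence")
  expect_equal(filt$reason[filt$locus == "Ga1a19"], "parent_missing")
  # 8/10 present passes at 0.75
  g2 <- fam$genotypes
  g2$allele_1[g2$individual %in% c("SON01", "SON02") & g2$locus == "Res22"] <- NA
  g2$allele_2[g2$individual %in% c("SON01", "SON02") & g2$locus == "Res22"] <- NA
  filt2 <- filter_family_loci("C1", fam$pedigree, g2, fam$registry)
  expect_true(filt2$retained[filt2$locus == "Res22"])
})

test_that("retained set at threshold 1 equals a brute-force row scan and the
          filter is monotone in the threshold", {
  set.seed(41)
  fam <- clean_hybrid_family(n_sons = 8)
  g <- fam$genotypes
  drop <- stats::runif(nrow(g)) < 0.5
  g$allele_1[drop] <- NA
  g$allele_2[drop] <- NA
  filt1 <- suppressWarnings(  # heavy missingness may retain nothing
    filter_family_loci("C1", fam$pedigree, g, fam$registry,
                       offspring_presence = 1.0))
  # independent scan: a locus survives iff no family member lacks a call
  ids <- c("DAD", "MOM", fam$pedigree$offspring_id)
  brute <- vapply(fam$registry$locus, function(loc) {
    all(vapply(ids, function(id) {
      r <- g[g$individual == id & g$locus == loc, ]
      nrow(r) == 1 && !is.na(r$allele_1)
    }, logical(1)))
  }, logical(1))
  expect_equal(filt1$retained, unname(brute))
  retained_at <- function(p) {
    f <- suppressWarnings(
      filter_family_loci("C1", fam$pedigree, g, fam$registry,
                         offspring_presence = p))
    f$locus[f$retained]
  }
  sets <- lapply(c(0, 0.25, 0.5, 0.75, 1), retained_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("null-allele signatures are flagged and Mendelian patterns are not", {
  reg <- locus_registry("A", list(character()), list(character()))
  flagged <- make_genotypes(list(
    DAD = c(A = "150/160"), MOM = c(A = "140/140"),
    K1 = c(A = "140/140"), K2 = c(A = "140/150")), reg)
  ped <- make_pedigree(c("K1", "K2"))
  hits <- screen_null_alleles("C1", ped, flagged, reg)
  expect_equal(hits$locus, "A")
  expect_equal(hits$null_parent, "father")
  clean <- make_genotypes(list(
    DAD = c(A = "150/160"), MOM = c(A = "140/140"),
    K1 = c(A = "140/150"), K2 = c(A = "140/160")), reg)
  expect_equal(nrow(screen_null_alleles("C1", ped, clean, reg)), 0L)
})

test_that("simulated null alleles are caught with no false flags", {
  cfg <- sim_config(n_fathers = 3, n_mothers = 3, females_per_father = 2,
                    offspring_per_cross = 20, null_rate = 0.1, seed = 5)
  sim <- simulate_system(cfg)
  events <- sim$truth$nulls$events
  expect_gt(nrow(events), 0)
  sig <- dplyr::filter(events, signature)
  ped <- sim$pedigree
  flagged <- purrr::map_dfr(unique(ped$cross_id), function(id) {
    f <- screen_null_alleles(id, ped, sim$genotypes, sim$registry)
    if (nrow(f)) dplyr::mutate(f, cross_id = id) else NULL
  })
  # every locus with a realized signature event in a family is flagged there
  sig_key <- unique(paste(
    ped$cross_id[match(sig$offspring_id, ped$offspring_id)], sig$locus))
  expect_true(all(sig_key %in% paste(flagged$cross_id, flagged$locus)))
  # and no flags at loci without any configured null in that family's parents
  des <- sim$truth$nulls$designations
  fam_parents <- dplyr::distinct(ped, cross_id, mother_id, father_id)
  clean_flags <- dplyr::anti_join(
    flagged,
    dplyr::bind_rows(
      dplyr::inner_join(fam_parents, des, by = c(mother_id = "parent_id"),
                        relationship = "many-to-many"),
      dplyr::inner_join(fam_parents, des, by = c(father_id = "parent_id"),
                        relationship = "many-to-many")),
    by = c("cross_id", "locus"))
  expect_equal(nrow(clean_flags), 0L)
})

test_that("phase_offspring resolves the diagnostic textbook cases", {
  reg <- waterfrog_loci()
  # RL son: paternal 301 is L-specific, maternal 287
  g <- make_genotypes(list(
    DAD = c(Rrid013A = "301/287", Res20 = "124/118"),
    MOM = c(Rrid013A = "287/293", Res20 = "118/122"),
    SON = c(Rrid013A = "301/287", Res20 = "124/118")), reg)
  ped <- make_pedigree("SON")
  hap <- phase_offspring("SON", "C1", ped, g, reg,
                         loci = c("Rrid013A", "Res20"),
                         cross_type = "hybrid", offspring_taxon = "RL")
  pat <- hap[hap$origin == "paternal_L" & hap$locus == "Rrid013A", ]
  mat <- hap[hap$origin == "maternal_R" & hap$locus == "Rrid013A", ]
  expect_equal(pat$status, "phased")
  expect_equal(pat$allele, "301")
  expect_equal(mat$allele, "287")
  # RR daughter of the same father: paternal allele is his R-specific 287
  g2 <- make_genotypes(list(
    DAD = c(Rrid013A = "301/287"), MOM = c(Rrid013A = "293/293"),
    DTR = c(Rrid013A = "287/293")), reg)
  hap2 <- phase_offspring("DTR", "C1", make_pedigree("DTR"), g2, reg,
                          loci = "Rrid013A", cross_type = "hybrid",
                          offspring_taxon = "RR")
  expect_equal(hap2$allele[hap2$origin == "paternal_R"], "287")
  expect_equal(hap2$allele[hap2$origin == "maternal_R"], "293")
})

test_that("phase_offspring validates its inputs", {
  fam <- clean_hybrid_family(2)
  expect_error(phase_offspring("GHOST", "C1", fam$pedigree, fam$genotypes,
                               fam$registry), "not in cross")
  expect_error(phase_offspring("SON01", "C1", fam$pedigree, fam$genotypes,
                               fam$registry, offspring_taxon = "unknown",
                               cross_type = "hybrid"),
               "cannot phase")
})

test_that("phase status and assignments match the enumeration oracle", {
  set.seed(101)
  n_families <- 200
  for (k in seq_len(n_families)) {
    fam <- random_small_family()
    loci <- fam$registry$locus
    geno <- fam$genotypes
    call2 <- function(id, loc) {
      r <- geno[geno$individual == id & geno$locus == loc, ]
      if (nrow(r) == 0) c(NA_character_, NA_character_)
      else c(r$allele_1, r$allele_2)
    }
    for (kid in fam$offspring) {
      taxon <- sample(c("RL", "RR"), 1)
      expected <- if (taxon == "RL") "L" else "R"
      hap <- phase_offspring(kid, "C1", fam$pedigree, geno, fam$registry,
                             loci = loci, cross_type = "hybrid",
                             offspring_taxon = taxon)
      for (loc in loci) {
        want <- oracle_phase_locus(call2(kid, loc), call2("MOM", loc),
                                   call2("DAD", loc), expected,
                                   fam$registry, loc)
        got <- hap[hap$locus == loc, ]
        expect_equal(unique(got$status), want$status,
                     info = sprintf("family %d, %s at %s", k, kid, loc))
        if (want$status == "phased") {
          expect_equal(got$allele[got$origin == "maternal_R"], want$maternal)
          expect_equal(got$allele[got$origin != "maternal_R"], want$paternal)
        }
      }
    }
  }
})

test_that("reassembly: phased maternal+paternal alleles equal the observed call", {
  sim <- simulate_system(sim_config(n_fathers = 2, n_mothers = 2,
                                    offspring_per_cross = 10,
                                    profile_probs = c(L = .5, R = .2, LR = .3),
                                    missing_rate = 0.05, seed = 31))
  pfs <- phase_families(sim$pedigree, sim$genotypes, sim$registry)
  hap <- dplyr::bind_rows(lapply(pfs, tidy)) |>
    dplyr::filter(status == "phased") |>
    dplyr::group_by(individual, locus) |>
    dplyr::summarise(rebuilt = paste(sort(allele), collapse = "/"),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(n == 2)
  obs <- sim$genotypes |>
    dplyr::mutate(observed = paste(pmin(allele_1, allele_2),
                                   pmax(allele_1, allele_2), sep = "/"))
  j <- dplyr::inner_join(hap, obs, by = c("individual", "locus"))
  expect_gt(nrow(j), 100)
  expect_equal(j$rebuilt, j$observed)
})

test_that("noiseless clonal family phases fully and exactly", {
  fam <- clean_hybrid_family(n_sons = 10)
  pf <- phase_family("C1", fam$pedigree, fam$genotypes, fam$registry)
  expect_equal(pf$cross_type, "hybrid")
  expect_equal(nrow(pf$conflicts), 0)
  pat <- pf$haplotypes[pf$haplotypes$origin == "paternal_L" &
                         pf$haplotypes$status == "phased", ]
  expect_equal(unname(fam$father_L[pat$locus]), pat$allele)
  # every son shares the identical inferred [L] haplotype
  per_son <- split(pat$allele, pat$individual)
  expect_equal(length(unique(per_son)), 1L)
  # the father's inferred haplotypes match his genotype split
  fL <- pf$father_haplotypes[pf$father_haplotypes$origin == "paternal_L", ]
  expect_equal(unname(fam$father_L[fL$locus]), fL$allele)
  fR <- pf$father_haplotypes[pf$father_haplotypes$origin == "paternal_R", ]
  expect_equal(unname(fam$father_R[fR$locus]), fR$allele)
})

test_that("amphispermic families recover two distinct paternal classes", {
  cfg <- sim_config(n_fathers = 1, n_mothers = 1, females_per_father = 1,
                    offspring_per_cross = 12,
                    profile_probs = c(L = 0, R = 0, LR = 1),
                    p_R_sperm = 0.5, seed = 13)
  sim <- simulate_system(cfg)
  classes <- unique(sim$truth$offspring$gamete_class)
  expect_setequal(classes, c("[L]", "[R]"))
  pf <- phase_family(sim$pedigree$cross_id[1], sim$pedigree, sim$genotypes,
                     sim$registry)
  truth_hap <- sim$truth$haplotypes
  pat <- pf$haplotypes[pf$haplotypes$origin %in% c("paternal_L", "paternal_R") &
                         pf$haplotypes$status == "phased", ]
  j <- dplyr::inner_join(pat, truth_hap,
                         by = c("individual", "origin", "locus"))
  expect_equal(j$allele.x, j$allele.y)
  expect_setequal(unique(pat$origin), c("paternal_L", "paternal_R"))
})

test_that("a single cross-genome paternal allele surfaces as a conflict", {
  reg <- waterfrog_loci()
  g <- read_genotypes(hemiphase_example("family60_genotypes_synthetic.csv"), reg)
  ped <- read_pedigree(hemiphase_example("family60_pedigree_synthetic.csv"))
  pf <- phase_family("60-2013", ped, g, reg)
  expect_equal(nrow(pf$conflicts), 1)
  expect_equal(pf$conflicts$offspring_id, "JUV19")
  expect_equal(pf$conflicts$locus, "Re1Caga10")
  expect_equal(pf$conflicts$type, "cross_genome")
  expect_match(pf$conflicts$description, "R-specific")
})

test_that("control RR x RR families phase with plain Mendelian logic", {
  reg <- locus_registry(c("A", "B"), list(character(), character()),
                        list(c("1", "2", "3", "4"), c("5", "6", "7", "8")))
  g <- make_genotypes(list(
    DAD = c(A = "1/2", B = "5/6"), MOM = c(A = "3/4", B = "5/6"),
    K1 = c(A = "1/3", B = "5/5"), K2 = c(A = "2/4", B = "5/6")), reg)
  ped <- make_pedigree(c("K1", "K2"))
  pf <- phase_family("C1", ped, g, reg, cross_type = "control")
  expect_equal(pf$cross_type, "control")
  k1a <- pf$haplotypes[pf$haplotypes$individual == "K1" &
                         pf$haplotypes$locus == "A", ]
  expect_equal(unique(k1a$status), "phased")
  # shared parental genotypes stay ambiguous
  k2b <- pf$haplotypes[pf$haplotypes$individual == "K2" &
                         pf$haplotypes$locus == "B", ]
  expect_equal(unique(k2b$status), "ambiguous")
})
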