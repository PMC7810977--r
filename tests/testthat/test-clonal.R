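# MLG keys and clustering, gamete profiles, leakage, linkage, summaries.

hap_row <- function(id, origin, loci, alleles, status = "phased") {
  tibble::tibble(individual = id, origin = origin, locus = loci,
                 allele = alleles, status = status)
}

test_that("MLG keys canonicalize locus order and missing data", {
  reg <- locus_registry(c("A", "B", "C"),
                        list(character(), character(), character()),
                        list("1", "2", "3"))
  h1 <- hap_row("x", "paternal_L", c("A", "B", "C"), c("1", "2", "3"))
  h2 <- hap_row("y", "paternal_L", c("C", "A", "B"), c("3", "1", "2"))
  keys <- mlg_key(dplyr::bind_rows(h1, h2), reg)
  expect_equal(keys$key[1], keys$key[2])
  h3 <- hap_row("z", "paternal_L", c("A", "B"), c("1", NA),
                status = c("phased", "missing"))
  k3 <- mlg_key(h3, reg)
  expect_equal(k3$key, "1:~:~")
  expect_equal(k3$missing_fraction, 2 / 3)
})

test_that("clonal haplotypes collapse to one key", {
  sim <- simulate_system(sim_config(n_fathers = 1, n_mothers = 2,
                                    females_per_father = 2,
                                    offspring_per_cross = 20,
                                    profile_probs = c(L = 1, R = 0, LR = 0),
                                    seed = 8))
  hapL <- dplyr::filter(sim$truth$haplotypes, origin == "paternal_L") |>
    dplyr::semi_join(sim$pedigree, by = c(individual = "offspring_id")) |>
    dplyr::mutate(status = "phased")
  keys <- mlg_key(hapL, sim$registry)
  expect_equal(dplyr::n_distinct(keys$key), 1L)
})

test_that("clustering merges identical haplotypes and splits variants", {
  reg <- locus_registry(c("A", "B"), list(character(), character()),
                        list("1", "2"))
  haps <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ hap_row(paste0("i", .x), "paternal_L",
                                  c("A", "B"), c("1", "2"))),
    hap_row("i6", "paternal_L", c("A", "B"), c("9", "2")))
  cl <- cluster_mlgs(haps, reg)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$n_members), c(1L, 5L))
})

test_that("haplotypes above the missing-data threshold are removed", {
  reg <- locus_registry(paste0("L", 1:10),
                        lapply(1:10, function(i) character()),
                        as.list(as.character(1:10)))
  full <- hap_row("ok", "paternal_L", paste0("L", 1:10), as.character(1:10))
  sparse <- hap_row("gappy", "paternal_L", paste0("L", 1:10),
                    c(as.character(1:3), rep(NA, 7)),
                    status = c(rep("phased", 3), rep("missing", 7)))
  cl <- cluster_mlgs(dplyr::bind_rows(full, sparse), reg, max_missing = 0.65)
  expect_equal(cl$excluded$individual, "gappy")
  expect_equal(nrow(cl$membership), 1L)
  expect_error(cluster_mlgs(sparse, reg, max_missing = 0.65), "threshold")
})

test_that("three simulated hemiclones are recovered despite missing data", {
  cfg <- sim_config(n_fathers = 6, n_mothers = 3, females_per_father = 2,
                    offspring_per_cross = 10,
                    profile_probs = c(L = 1, R = 0, LR = 0),
                    n_hemiclones = 3, missing_rate = 0.2, seed = 12)
  sim <- simulate_system(cfg)
  pfs <- phase_families(sim$pedigree, sim$genotypes, sim$registry)
  hapL <- dplyr::bind_rows(lapply(pfs, tidy)) |>
    dplyr::filter(origin == "paternal_L")
  cl <- cluster_mlgs(hapL, sim$registry)
  expect_equal(nrow(cl$clusters), 3L)
  # membership agrees with the fathers' hemiclone assignment for every
  # haplotype whose cluster choice was unambiguous (a heavily missing
  # haplotype compatible with several clusters joins the first and is
  # flagged instead)
  truth <- sim$truth$offspring |>
    dplyr::left_join(sim$truth$hemiclones, by = "father_id")
  j <- dplyr::inner_join(dplyr::filter(cl$membership, !ambiguous), truth,
                         by = c(individual = "offspring_id"))
  tab <- table(j$cluster_id, j$hemiclone)
  expect_equal(sum(tab > 0), 3L)  # one-to-one cluster/hemiclone mapping
})

test_that("cluster output is invariant to haplotype input order", {
  cfg <- sim_config(n_fathers = 4, n_mothers = 2, offspring_per_cross = 8,
                    profile_probs = c(L = 1, R = 0, LR = 0),
                    n_hemiclones = 2, missing_rate = 0.3, seed = 14)
  sim <- simulate_system(cfg)
  hapL <- dplyr::filter(sim$truth$haplotypes, origin == "paternal_L") |>
    dplyr::semi_join(sim$pedigree, by = c(individual = "offspring_id")) |>
    dplyr::mutate(status = "phased")
  set.seed(1)
  shuffled <- hapL[sample(nrow(hapL)), ]
  expect_equal(cluster_mlgs(hapL, sim$registry)$membership,
               cluster_mlgs(shuffled, sim$registry)$membership)
  # every retained haplotype sits in exactly one cluster
  cl <- cluster_mlgs(hapL, sim$registry)
  expect_equal(nrow(cl$membership) + nrow(cl$excluded),
               dplyr::n_distinct(hapL$individual))
})

test_that("gamete profiles follow offspring taxa pooled across crosses", {
  calls <- tibble::tibble(
    cross_id = c("c1", "c1", "c2", "c2", "c3"),
    father_id = c("M1", "M1", "M1", "M2", "M3"),
    father_taxon = "RL",
    taxon = c("RL", "RL", "RR", "RL", "unknown"))
  prof <- classify_gamete_profiles(calls)
  m1 <- prof[prof$father_id == "M1", ]
  expect_true(m1$amphispermic)
  expect_equal(m1$classes, "[L],[R]")
  expect_equal(m1$n_offspring, 3L)
  m2 <- prof[prof$father_id == "M2", ]
  expect_equal(m2$classes, "[L]")
  expect_false(m2$amphispermic)
  # unknown-taxon offspring contribute nothing; M3 has no evidence
  expect_false("M3" %in% prof$father_id)
  expect_error(classify_gamete_profile("M3", calls), "no classified offspring")
})

test_that("leakage detection is silent on a clean clonal family", {
  fam <- clean_hybrid_family(6)
  pf <- phase_family("C1", fam$pedigree, fam$genotypes, fam$registry)
  expect_equal(nrow(detect_leakage(pf, fam$registry)), 0L)
})

test_that("the packaged single-leak family yields exactly one event", {
  reg <- waterfrog_loci()
  g <- read_genotypes(hemiphase_example("family60_genotypes_synthetic.csv"), reg)
  ped <- read_pedigree(hemiphase_example("family60_pedigree_synthetic.csv"))
  ev <- detect_leakage(phase_family("60-2013", ped, g, reg), reg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$offspring_id, "JUV19")
  expect_equal(ev$locus, "Re1Caga10")
  expect_equal(ev$expected_genome, "[L]")
  expect_equal(ev$observed_class, "r_specific")
})

test_that("two-point rf is zero for clonal gametes, including the 2-gamete floor", {
  reg <- locus_registry(c("A", "B"), list(character(), character()),
                        list(c("1", "9"), c("2", "8")))
  clonal <- purrr::map_dfr(1:4, ~ hap_row(paste0("g", .x), "paternal_L",
                                          c("A", "B"), c("1", "2")))
  parent <- genotype_table(
    tibble::tibble(individual = "P", locus = c("A", "B"),
                   allele_1 = c("1", "2"), allele_2 = c("9", "8")), reg)
  rf <- two_point_rf(clonal, parent = parent)
  expect_equal(tidy(rf)$r_hat, 0)
  # two complementary gametes: the phase-minimising pairing gives 0
  comp <- dplyr::bind_rows(
    hap_row("g1", "paternal_L", c("A", "B"), c("1", "2")),
    hap_row("g2", "paternal_L", c("A", "B"), c("9", "8")))
  expect_equal(tidy(two_point_rf(comp, parent = parent))$r_hat, 0)
  # a single gamete is not enough
  one <- hap_row("g1", "paternal_L", c("A", "B"), c("1", "2"))
  expect_true(is.na(tidy(two_point_rf(one, parent = parent))$r_hat))
  expect_error(two_point_rf(one[1, ], parent = parent), "two informative")
})

test_that("unlinked maternal gametes estimate rf near one half", {
  reg <- diverse_registry()
  cfg <- sim_config(n_fathers = 1, n_mothers = 1, females_per_father = 1,
                    offspring_per_cross = 300,
                    profile_probs = c(L = 1, R = 0, LR = 0),
                    registry = reg, seed = 2)
  sim <- simulate_system(cfg)
  mat <- dplyr::filter(sim$truth$haplotypes, origin == "maternal_R") |>
    dplyr::semi_join(sim$pedigree, by = c(individual = "offspring_id")) |>
    dplyr::mutate(status = "phased")
  mother <- dplyr::filter(sim$genotypes, individual == "F01")
  r <- tidy(two_point_rf(mat, parent = mother))$r_hat
  bound <- 3 * sqrt(0.25 / 300)
  expect_true(all(r >= 0.5 - bound & r <= 0.5))
})

test_that("leakage lifts clonal rf estimates off zero, monotonically", {
  rf_at <- function(eps, seed = 33) {
    cfg <- sim_config(n_fathers = 1, n_mothers = 1, females_per_father = 1,
                      offspring_per_cross = 500,
                      profile_probs = c(L = 1, R = 0, LR = 0),
                      leak_rate = eps, seed = seed)
    sim <- simulate_system(cfg)
    pat <- dplyr::filter(sim$truth$haplotypes, origin == "paternal_L") |>
      dplyr::semi_join(sim$pedigree, by = c(individual = "offspring_id")) |>
      dplyr::mutate(status = "phased")
    father <- dplyr::filter(sim$genotypes, individual == "M01")
    mean(tidy(two_point_rf(pat, parent = father))$r_hat, na.rm = TRUE)
  }
  r0 <- rf_at(0)
  r5 <- rf_at(0.05)
  expect_equal(r0, 0)
  expect_gt(r5, 0)
})

test_that("family summary reproduces the published cross table totals", {
  fs <- summarize_families(expand_cross_table(waterfrog_crosses()))
  tot <- glance(fs)
  expect_equal(tot$n_crosses, 17L)
  expect_equal(tot$rr_daughters, 67L)
  expect_equal(tot$rl_sons, 207L)
  expect_equal(tot$sexed_offspring, 274L)
  expect_equal(tot$undetermined_offspring, 4L)
  expect_equal(tot$n_sex_discordant, 0L)
  by_cross <- tidy(fs)
  expect_equal(sum(dplyr::select(by_cross, dplyr::matches("^(rr|rl)_"))),
               tot$n_offspring)  # conservation over cells
  expect_equal(by_cross$rl_male[by_cross$cross_id == "42-2013"], 64L)
})

test_that("summary cells match simulation truth", {
  sim <- simulate_system(sim_config(n_fathers = 3, n_mothers = 2,
                                    offspring_per_cross = 15,
                                    profile_probs = c(L = .5, R = .2, LR = .3),
                                    seed = 19))
  calls <- offspring_calls(sim$pedigree, sim$genotypes, sim$registry)
  tot <- glance(summarize_families(calls))
  truth <- sim$truth$offspring
  expect_equal(tot$n_offspring, nrow(truth))
  expect_equal(tot$rr_daughters,
               sum(truth$taxon == "RR" & truth$sex == "female"))
  expect_equal(tot$rl_sons, sum(truth$taxon == "RL" & truth$sex == "male"))
  expect_equal(glance(summarize_families(calls[0, ]))$n_offspring, 0L)
})

test_that("tidiers and autoplot methods return well-formed objects", {
  fs <- summarize_families(expand_cross_table(waterfrog_crosses()))
  expect_s3_class(tidy(fs), "tbl_df")
  expect_equal(nrow(glance(fs)), 1L)
  expect_s3_class(autoplot(fs), "ggplot")
  fam <- clean_hybrid_family(4)
  pf <- phase_family("C1", fam$pedigree, fam$genotypes, fam$registry)
  expect_s3_class(tidy(pf), "tbl_df")
  expect_equal(glance(pf)$n_conflicts, 0L)
  hapL <- dplyr::filter(tidy(pf), origin == "paternal_L")
  cl <- cluster_mlgs(hapL, fam$registry)
  expect_s3_class(autoplot(cl), "ggplot")
  reg <- diverse_registry(3)
  gam <- purrr::map_dfr(1:3, ~ hap_row(paste0("g", .x), "paternal_L",
                                       reg$locus, c("140", "180", "220")))
  rf <- two_point_rf(gam)
  m <- as.matrix(rf)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), setNames(rep(0, 3), reg$locus))
  expect_s3_class(autoplot(rf), "ggplot")
})
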