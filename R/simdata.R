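# Synthetic hybridogenetic cross simulator with full ground truth.
#
# Emulates the experimental design: hybrid RL males, each carrying one
# hemiclonal [L] haplotype and one clonal [R] haplotype, crossed with sexual
# RR females whose gametes recombine; offspring sex follows the XX-XY model
# with the male-determining factor on the [L] genome. Optional artifacts:
# genome leakage, null alleles, and missing data.

#' Default non-diagnostic allele pools
#'
#' Published diagnostic allele lists do not cover the alleles the two species
#' share; real genotypes contain both. This builds a deterministic set of
#' plausible extra fragment lengths per locus (below the registry's range,
#' avoiding collisions) to serve as the shared (non-diagnostic) pool.
#'
#' @param registry A `hemi_registry`.
#' @param n_alleles Shared alleles per locus (default 4).
#' @return Named list locus -> character vector of allele tokens.
#' @export
default_shared_pools <- function(registry, n_alleles = 4) {
  diag <- registry_alleles(registry)
  out <- lapply(registry$locus, function(loc) {
    used <- suppressWarnings(as.numeric(diag$allele[diag$locus == loc]))
    used <- used[!is.na(used)]
    base <- if (length(used) > 0) min(used) else 100
    cand <- seq(max(3, base - 3 * n_alleles - 6), by = 3, length.out = n_alleles + 4)
    cand <- setdiff(as.character(cand), diag$allele[diag$locus == loc])
    utils::head(cand, n_alleles)
  })
  setNames(out, registry$locus)
}

#' Simulation configuration
#'
#' Defines the crossing design and noise model for [simulate_system()]. The
#' defaults describe a generic small experiment; [study_like_config()]
#' returns the configuration matching the published design.
#'
#' @param n_fathers Number of hybrid (RL) fathers.
#' @param n_mothers Number of sexual RR mothers shared across crosses.
#' @param females_per_father Integer vector; each father is crossed with
#'   `sample(females_per_father, 1)` distinct mothers (2-3 in the study).
#' @param offspring_per_cross Integer vector of candidate clutch sizes; each
#'   cross samples one.
#' @param profile_probs Probabilities that a father produces only [L] sperm,
#'   only [R] sperm, or both (amphispermy); must sum to 1.
#' @param p_R_sperm For amphispermic fathers, the per-meiosis probability of
#'   an [R] sperm.
#' @param registry Locus registry supplying the diagnostic allele pools.
#' @param shared_pools Named list locus -> non-diagnostic allele pool
#'   (defaults to [default_shared_pools()]). Sampling within every pool is
#'   uniform (published tables list alleles, not frequencies).
#' @param maternal_map Tibble `locus`, `group`, `rf_to_prev` describing the
#'   female linkage map; within a group, each locus recombines with the
#'   previous one at rate `rf_to_prev`. Default: all loci unlinked.
#' @param leak_rate Per-meiosis, per-candidate-locus probability that a
#'   clonal paternal gamete carries the father's other-genome allele instead.
#'   Candidate loci are those where that other-genome allele is
#'   species-diagnostic — the only class of substitution observable as
#'   leakage (the real observed event is of this class).
#' @param null_rate Per (parent, locus) probability that one of the parent's
#'   two alleles is a null: invisible in the parent (it types as an apparent
#'   homozygote) and in every offspring that inherits it.
#' @param missing_rate Per (individual, locus) probability of a missing call,
#'   applied last.
#' @param include_control Add one sexual RR control male crossed with every
#'   mother.
#' @param n_hemiclones Number of distinct [L] hemiclone haplotypes; fathers
#'   are assigned cyclically.
#' @param seed Integer seed; all randomness derives from it (per-cross
#'   substreams are hashed from it, so family contents do not depend on
#'   generation order).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fathers = 4, n_mothers = 3,
                       females_per_father = 2:3,
                       offspring_per_cross = c(5, 10, 20),
                       profile_probs = c(L = 0.75, R = 1 / 12, LR = 1 / 6),
                       p_R_sperm = 0.5,
                       registry = waterfrog_loci(),
                       shared_pools = NULL,
                       maternal_map = NULL,
                       leak_rate = 0, null_rate = 0, missing_rate = 0,
                       include_control = FALSE, n_hemiclones = 1,
                       seed = 1L) {
  stopifnot(n_fathers >= 1, n_mothers >= 1,
            all(females_per_father >= 1), all(offspring_per_cross >= 0))
  if (abs(sum(profile_probs) - 1) > 1e-8 || any(profile_probs < 0)) {
    abort("profile_probs must be non-negative and sum to 1")
  }
  for (p in c(p_R_sperm, leak_rate, null_rate, missing_rate)) {
    if (p < 0 || p > 1) abort("rates must be in [0, 1]")
  }
  shared_pools <- shared_pools %||% default_shared_pools(registry)
  maternal_map <- maternal_map %||%
    tibble(locus = registry$locus, group = seq_along(registry$locus),
           rf_to_prev = NA_real_)
  if (any(stats::na.omit(maternal_map$rf_to_prev) < 0) ||
      any(stats::na.omit(maternal_map$rf_to_prev) > 0.5)) {
    abort("recombination fractions must lie in [0, 0.5]")
  }
  structure(list(
    n_fathers = n_fathers, n_mothers = n_mothers,
    females_per_father = females_per_father,
    offspring_per_cross = offspring_per_cross,
    profile_probs = profile_probs, p_R_sperm = p_R_sperm,
    registry = registry, shared_pools = shared_pools,
    maternal_map = maternal_map, leak_rate = leak_rate,
    null_rate = null_rate, missing_rate = missing_rate,
    include_control = include_control, n_hemiclones = n_hemiclones,
    seed = as.integer(seed)), class = "sim_config")
}

#' Configuration matching the published crossing design
#'
#' 16 hybrid fathers, nine mothers reused across crosses (two or three
#' females per father), one RR control male crossed with every female, the
#' published 15-locus registry as allele pools, clutch sizes resampled from
#' the observed per-cross totals, and father gamete-profile probabilities set
#' to the observed 9:1:2 pattern ([L]-only : [R]-only : amphispermic among 12
#' fathers).
#'
#' @param seed Integer seed.
#' @param noise With noise (`TRUE`, default) moderate missing-data, null-
#'   allele and leakage rates emulate real genotyping; `FALSE` gives the
#'   clean version used for exact recovery checks.
#' @return A `sim_config`.
#' @export
study_like_config <- function(seed = 1L, noise = TRUE) {
  observed_sizes <- c(20, 3, 1, 2, 24, 64, 2, 20, 3, 22, 26, 49, 3, 19, 2, 3, 17)
  sim_config(
    n_fathers = 16, n_mothers = 9, females_per_father = 2:3,
    offspring_per_cross = observed_sizes,
    profile_probs = c(L = 9 / 12, R = 1 / 12, LR = 2 / 12),
    p_R_sperm = 0.5,
    registry = waterfrog_loci(),
    leak_rate = if (noise) 5e-4 else 0,
    null_rate = if (noise) 0.01 else 0,
    missing_rate = if (noise) 0.03 else 0,
    include_control = TRUE, n_hemiclones = 1, seed = seed)
}

# Draw one haploid genome: L-side genomes use the L-specific pool where one
# exists (shared otherwise); R-side genomes the R-specific pool likewise.
.draw_haplotype <- function(config, side) {
  reg <- config$registry
  vapply(seq_len(nrow(reg)), function(i) {
    pool <- if (side == "L") reg$l_alleles[[i]] else reg$r_alleles[[i]]
    if (length(pool) == 0) pool <- config$shared_pools[[reg$locus[i]]]
    sample(pool, 1)
  }, character(1))
}

# Recombinant gamete from two haplotypes under the configured female map.
.recombine <- function(h1, h2, map, loci) {
  gam <- character(length(loci))
  names(gam) <- loci
  for (grp in split(seq_len(nrow(map)), map$group)) {
    cur <- sample(1:2, 1)
    for (j in grp) {
      rf <- map$rf_to_prev[j]
      if (j != grp[1] && !is.na(rf) && stats::runif(1) < rf) cur <- 3 - cur
      else if (j != grp[1] && is.na(rf)) cur <- sample(1:2, 1)
      gam[map$locus[j]] <- if (cur == 1) h1[map$locus[j]] else h2[map$locus[j]]
    }
  }
  gam[loci]
}

#' Simulate a full hybridogenetic crossing experiment
#'
#' Generates parents, crosses, offspring genotypes and complete ground truth
#' under a [sim_config()]. Mothers are sexual RR (two recombining R
#' haplotypes); hybrid fathers carry one hemiclonal [L] and one clonal [R]
#' haplotype, transmitted without recombination; rare leakage substitutes the
#' father's other-genome allele at species-diagnostic loci; null alleles
#' mask one parental allele (apparent homozygotes); missingness is applied
#' last. Identical configurations (including seed) give identical output.
#'
#' @param config A `sim_config`.
#' @return List of class `hemi_sim`: `genotypes` (observed genotype table),
#'   `pedigree`, `registry`, and `truth` (class `sim_truth`: `parents`,
#'   `offspring`, `haplotypes` in long form, `leaks`, `nulls`,
#'   `hemiclones`, plus the `config`).
#' @export
simulate_system <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  reg <- config$registry
  loci <- reg$locus
  set.seed(config$seed)

  # Hemiclone [L] haplotypes, distinct by redraw if colliding.
  hemiclones <- list()
  for (k in seq_len(config$n_hemiclones)) {
    for (attempt in 1:100) {
      h <- setNames(.draw_haplotype(config, "L"), loci)
      if (!any(vapply(hemiclones, identical, logical(1), h))) break
    }
    hemiclones[[k]] <- h
  }

  father_ids <- sprintf("M%02d", seq_len(config$n_fathers))
  mother_ids <- sprintf("F%02d", seq_len(config$n_mothers))
  fathers <- purrr::map(setNames(father_ids, father_ids), function(id) {
    k <- ((match(id, father_ids) - 1) %% config$n_hemiclones) + 1
    list(id = id, hemiclone = k,
         L = hemiclones[[k]],
         R = setNames(.draw_haplotype(config, "R"), loci),
         profile = sample(names(config$profile_probs), 1,
                          prob = config$profile_probs))
  })
  mothers <- purrr::map(setNames(mother_ids, mother_ids), function(id) {
    list(id = id,
         h1 = setNames(.draw_haplotype(config, "R"), loci),
         h2 = setNames(.draw_haplotype(config, "R"), loci))
  })
  control <- if (config$include_control) {
    list(id = "CTRL", h1 = setNames(.draw_haplotype(config, "R"), loci),
         h2 = setNames(.draw_haplotype(config, "R"), loci))
  } else NULL

  # Null-allele designations: (parent, locus, which haplotype copy).
  all_parents <- c(father_ids, mother_ids)
  null_mask <- purrr::map_dfr(all_parents, function(id) {
    hit <- stats::runif(length(loci)) < config$null_rate
    if (!any(hit)) return(NULL)
    tibble(parent_id = id, locus = loci[hit],
           copy = sample(1:2, sum(hit), replace = TRUE))
  })
  null_keys <- if (nrow(null_mask) > 0) {
    paste(null_mask$parent_id, null_mask$locus, null_mask$copy)
  } else character()
  is_null <- function(id, locus, copy) {
    paste(id, locus, copy) %in% null_keys
  }

  # Cross structure.
  crosses <- purrr::imap_dfr(fathers, function(f, id) {
    n_f <- sample(config$females_per_father, 1)
    n_f <- min(n_f, config$n_mothers)
    tibble(father_id = id, mother_id = sample(mother_ids, n_f))
  })
  if (!is.null(control)) {
    crosses <- bind_rows(crosses,
                         tibble(father_id = "CTRL", mother_id = mother_ids))
  }
  crosses$cross_id <- sprintf("X%03d", seq_len(nrow(crosses)))

  map <- config$maternal_map
  leak_cand_tbl <- purrr::map(fathers, function(f) {
    list("[L]" = loci[allele_class(reg, loci, unname(f$R)) == "r_specific"],
         "[R]" = loci[allele_class(reg, loci, unname(f$L)) == "l_specific"])
  })
  leak_candidates <- function(father, class) leak_cand_tbl[[father$id]][[class]]

  offspring_rows <- list(); hap_rows <- list(); leak_rows <- list()
  geno_rows <- list(); null_event_rows <- list()

  observed_parent_geno <- function(id, haps) {
    # haps: list of two named allele vectors (copy 1, copy 2)
    purrr::map_dfr(loci, function(loc) {
      a <- c(haps[[1]][loc], haps[[2]][loc])
      vis <- a[!c(is_null(id, loc, 1), is_null(id, loc, 2))]
      if (length(vis) == 0) vis <- c(NA_character_, NA_character_)
      if (length(vis) == 1) vis <- rep(vis, 2)  # apparent homozygote
      tibble(individual = id, locus = loc, allele_1 = vis[1], allele_2 = vis[2])
    })
  }

  for (f in fathers) {
    geno_rows[[length(geno_rows) + 1]] <-
      observed_parent_geno(f$id, list(f$L, f$R))
    hap_rows[[length(hap_rows) + 1]] <- bind_rows(
      tibble(individual = f$id, origin = "paternal_L", locus = loci,
             allele = unname(f$L)),
      tibble(individual = f$id, origin = "paternal_R", locus = loci,
             allele = unname(f$R)))
  }
  for (m in mothers) {
    geno_rows[[length(geno_rows) + 1]] <-
      observed_parent_geno(m$id, list(m$h1, m$h2))
    hap_rows[[length(hap_rows) + 1]] <- bind_rows(
      tibble(individual = m$id, origin = "maternal_h1", locus = loci,
             allele = unname(m$h1)),
      tibble(individual = m$id, origin = "maternal_h2", locus = loci,
             allele = unname(m$h2)))
  }
  if (!is.null(control)) {
    geno_rows[[length(geno_rows) + 1]] <-
      observed_parent_geno("CTRL", list(control$h1, control$h2))
  }

  n_loci <- length(loci)
  for (i in seq_len(nrow(crosses))) {
    cr <- crosses[i, ]
    set.seed(stable_hash(c(config$seed, cr$cross_id)))
    n_off <- if (length(config$offspring_per_cross) == 1) {
      config$offspring_per_cross
    } else sample(config$offspring_per_cross, 1)
    if (n_off == 0) next
    mother <- mothers[[cr$mother_id]]
    is_control <- cr$father_id == "CTRL"
    father <- if (is_control) control else fathers[[cr$father_id]]
    oid <- sprintf("%s_J%02d", cr$cross_id, seq_len(n_off))
    class <- character(n_off); sex <- character(n_off); taxon <- character(n_off)
    pat_origin <- character(n_off)
    mat_g <- pat_g <- a1 <- a2 <- matrix(NA_character_, n_off, n_loci,
                                         dimnames = list(oid, loci))
    for (j in seq_len(n_off)) {
      # paternal gamete
      if (is_control) {
        pat <- .recombine(father$h1, father$h2, map, loci)
        class[j] <- "R_sexual"
        sex[j] <- if (stats::runif(1) < 0.5) "male" else "female"
        taxon[j] <- "RR"
        pat_origin[j] <- "paternal_R"
        pat_null <- rep(FALSE, n_loci)
      } else {
        class[j] <- switch(father$profile,
                           L = "[L]", R = "[R]",
                           LR = if (stats::runif(1) < config$p_R_sperm) "[R]" else "[L]")
        pat <- if (class[j] == "[L]") father$L else father$R
        if (config$leak_rate > 0) {
          cand <- leak_candidates(father, class[j])
          hit <- cand[stats::runif(length(cand)) < config$leak_rate]
          for (loc in hit) {
            other <- if (class[j] == "[L]") father$R[loc] else father$L[loc]
            leak_rows[[length(leak_rows) + 1]] <- tibble(
              cross_id = cr$cross_id, offspring_id = oid[j], locus = loc,
              gamete_class = class[j], clonal_allele = unname(pat[loc]),
              leaked_allele = unname(other))
            pat[loc] <- other
          }
        }
        sex[j] <- if (class[j] == "[L]") "male" else "female"
        taxon[j] <- if (class[j] == "[L]") "RL" else "RR"
        pat_origin[j] <- if (class[j] == "[L]") "paternal_L" else "paternal_R"
        pat_null <- is_null(cr$father_id, loci,
                            if (class[j] == "[L]") 1L else 2L)
      }
      # maternal gamete; copy path kept for null masking
      mat_path <- .recombine(setNames(rep("1", n_loci), loci),
                             setNames(rep("2", n_loci), loci), map, loci)
      mat <- ifelse(mat_path == "1", mother$h1[loci], mother$h2[loci])
      mat_null <- is_null(cr$mother_id, loci, as.integer(mat_path))
      mat_g[j, ] <- unname(mat)
      pat_g[j, ] <- unname(pat[loci])

      # observed genotype: null masking (apparent homozygotes), one parent
      # visible -> duplicated allele, both null -> dropout
      v1 <- ifelse(mat_null, NA_character_, unname(mat))
      v2 <- ifelse(pat_null, NA_character_, unname(pat[loci]))
      single <- xor(mat_null, pat_null)
      vis <- ifelse(is.na(v1), v2, v1)
      a1[j, ] <- ifelse(single, vis, v1)
      a2[j, ] <- ifelse(single, vis, v2)
      if (any(single)) {
        null_event_rows[[length(null_event_rows) + 1]] <- tibble(
          cross_id = cr$cross_id, offspring_id = oid[j], locus = loci[single],
          null_parent = ifelse(mat_null[single], "mother", "father"),
          observed_allele = vis[single])
      }
    }
    offspring_rows[[length(offspring_rows) + 1]] <- tibble(
      cross_id = cr$cross_id, offspring_id = oid,
      father_id = cr$father_id, mother_id = cr$mother_id,
      gamete_class = class, sex = sex, taxon = taxon)
    hap_rows[[length(hap_rows) + 1]] <- tibble(
      individual = rep(oid, each = 2 * n_loci),
      origin = rep(c(rbind(rep("maternal_R", n_off), pat_origin)),
                   each = n_loci),
      locus = rep(loci, 2 * n_off),
      allele = c(t(cbind(mat_g, pat_g))))
    geno_rows[[length(geno_rows) + 1]] <- tibble(
      individual = rep(oid, each = n_loci), locus = rep(loci, n_off),
      allele_1 = c(t(a1)), allele_2 = c(t(a2)))
  }

  geno <- bind_rows(geno_rows)
  if (config$missing_rate > 0) {
    set.seed(stable_hash(c(config$seed, "missingness")))
    drop <- stats::runif(nrow(geno)) < config$missing_rate
    geno$allele_1[drop] <- NA_character_
    geno$allele_2[drop] <- NA_character_
  }
  genotypes <- genotype_table(geno, reg)

  offspring <- bind_rows(offspring_rows)
  pedigree <- select(offspring, "cross_id", "mother_id", "father_id",
                     "offspring_id", "sex")
  nulls <- list(
    designations = null_mask,
    events = bind_rows(null_event_rows))
  # signature events: apparent homozygote allele invisible in the null parent
  if (nrow(nulls$events) > 0) {
    parent_obs <- genotypes
    nulls$events$signature <- purrr::pmap_lgl(nulls$events, function(...) {
      e <- list(...)
      ped_row <- pedigree[pedigree$offspring_id == e$offspring_id, ]
      pid <- if (e$null_parent == "mother") ped_row$mother_id else ped_row$father_id
      obs <- parent_obs[parent_obs$individual == pid & parent_obs$locus == e$locus, ]
      off <- parent_obs[parent_obs$individual == e$offspring_id &
                          parent_obs$locus == e$locus, ]
      # detectable only while the null parent is fully typed and the
      # offspring still shows the apparent homozygote
      nrow(obs) == 1 && !anyNA(c(obs$allele_1, obs$allele_2)) &&
        nrow(off) == 1 && identical(off$allele_1, e$observed_allele) &&
        identical(off$allele_2, e$observed_allele) &&
        !e$observed_allele %in% c(obs$allele_1, obs$allele_2)
    })
  }

  truth <- structure(list(
    parents = tibble(
      individual = c(father_ids, mother_ids, if (!is.null(control)) "CTRL"),
      role = c(rep("father", length(father_ids)),
               rep("mother", length(mother_ids)),
               if (!is.null(control)) "control_father"),
      profile = c(vapply(fathers, function(f) f$profile, character(1)),
                  rep(NA_character_, length(mother_ids) + !is.null(control)))),
    offspring = offspring,
    haplotypes = bind_rows(hap_rows),
    leaks = if (length(leak_rows)) bind_rows(leak_rows) else
      tibble(cross_id = character(), offspring_id = character(),
             locus = character(), gamete_class = character(),
             clonal_allele = character(), leaked_allele = character()),
    nulls = nulls,
    hemiclones = tibble(father_id = father_ids,
                        hemiclone = vapply(fathers, function(f) f$hemiclone,
                                           numeric(1))),
    config = config), class = "sim_truth")

  structure(list(genotypes = genotypes, pedigree = pedigree, registry = reg,
                 truth = truth), class = "hemi_sim")
}

#' @export
print.hemi_sim <- function(x, ...) {
  cat(sprintf("<hemi_sim> %d crosses, %d offspring, %d loci (seed %d)\n",
              dplyr::n_distinct(x$pedigree$cross_id), nrow(x$pedigree),
              nrow(x$registry), x$truth$config$seed))
  invisible(x)
}
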