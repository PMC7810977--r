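# Family-wise phasing of non-Mendelian backcross genotypes.
#
# The engine splits each offspring's diploid genotype into a maternal and a
# paternal haplotype by enumerating, locus by locus, the assignments of the
# observed allele pair to (maternal, paternal) that are consistent with the
# parents' genotypes, then narrowing by species-specificity: in an R[L] x RR
# cross the paternal allele of an RL offspring must be L-specific, or
# non-diagnostic but present only in father and offspring, never the mother.

.family <- function(pedigree, cross_id) {
  rows <- filter(validate_pedigree(pedigree), .data$cross_id == !!cross_id)
  if (nrow(rows) == 0) abort(sprintf("cross '%s' not in pedigree", cross_id))
  list(cross_id = cross_id,
       mother_id = rows$mother_id[1],
       father_id = rows$father_id[1],
       offspring = select(rows, "offspring_id", "sex"))
}

# (individual, locus) -> character(2) lookup (NA-padded).
.geno_env <- function(genotypes) {
  keys <- paste(genotypes$individual, genotypes$locus, sep = "\r")
  vals <- purrr::map2(genotypes$allele_1, genotypes$allele_2, c)
  env <- list2env(setNames(vals, keys), parent = emptyenv())
  function(ind, locus) {
    get0(paste(ind, locus, sep = "\r"), envir = env,
         ifnotfound = c(NA_character_, NA_character_))
  }
}

# Shared precomputations for phasing a whole dataset; built once by
# phase_families() and threaded through the per-family calls.
.phase_context <- function(genotypes, registry, min_support = 2) {
  list(geno = .geno_env(genotypes),
       taxa = assign_taxa(genotypes, registry, min_support = min_support),
       lk = .allele_class_lookup(registry))
}

#' Filter loci for one family
#'
#' A locus is retained for phasing when both parents have a non-missing call,
#' at least `offspring_presence` of the family's offspring have non-missing
#' calls, and (SNP mode) at most two distinct alleles segregate within the
#' family. Dropped loci carry a reason.
#'
#' @param cross_id Cross to filter.
#' @param pedigree Pedigree tibble ([read_pedigree()]).
#' @param genotypes Genotype table.
#' @param registry A `hemi_registry`.
#' @param offspring_presence Minimum fraction of offspring with a non-missing
#'   call (default 0.75, the filter used for the phased dataset; raising it
#'   never grows the retained set).
#' @param snp_mode Apply the within-family biallelic check; defaults to the
#'   genotype table's marker mode.
#' @param context Precomputed lookup tables shared across families (built by
#'   [phase_families()]); `NULL` builds them on the fly.
#' @return Tibble `locus`, `retained`, `reason`
#'   (`NA`, `"parent_missing"`, `"offspring_presence"`, `"multiallelic"`).
#' @export
filter_family_loci <- function(cross_id, pedigree, genotypes, registry,
                               offspring_presence = 0.75, snp_mode = NULL,
                               context = NULL) {
  snp_mode <- snp_mode %||% (marker_mode(genotypes) == "snp")
  fam <- .family(pedigree, cross_id)
  geno <- context$geno %||% .geno_env(genotypes)
  present <- function(ind, locus) any(!is.na(geno(ind, locus)))
  out <- purrr::map_dfr(registry$locus, function(loc) {
    parents_ok <- present(fam$mother_id, loc) && present(fam$father_id, loc)
    n_off <- nrow(fam$offspring)
    frac <- if (n_off == 0) 1 else
      mean(vapply(fam$offspring$offspring_id, present, logical(1), locus = loc))
    fam_alleles <- unique(stats::na.omit(unlist(
      lapply(c(fam$mother_id, fam$father_id, fam$offspring$offspring_id),
             geno, locus = loc))))
    reason <- if (!parents_ok) "parent_missing"
    else if (frac < offspring_presence) "offspring_presence"
    else if (snp_mode && length(fam_alleles) > 2) "multiallelic"
    else NA_character_
    tibble(locus = loc, retained = is.na(reason), reason = reason)
  })
  if (!any(out$retained)) {
    warn(sprintf("no loci retained for cross '%s'", cross_id))
  }
  out
}

#' Screen a family's loci for null-allele artifacts
#'
#' A null allele in one parent makes heterozygous (null/allele) progeny look
#' homozygous. The signature: an offspring apparently homozygous for an allele
#' that one parent does not carry while the other parent does. Flagged loci
#' should be dropped from phasing.
#'
#' @inheritParams filter_family_loci
#' @param loci Loci to screen; defaults to all registry loci at which both
#'   parents have full (two-allele) calls.
#' @return Tibble `locus`, `null_parent` (`"mother"`/`"father"`),
#'   `n_offspring_evidence`, `allele`.
#' @export
screen_null_alleles <- function(cross_id, pedigree, genotypes, registry,
                                loci = NULL, context = NULL) {
  fam <- .family(pedigree, cross_id)
  geno <- context$geno %||% .geno_env(genotypes)
  full <- function(ind, locus) !anyNA(geno(ind, locus))
  loci <- loci %||% registry$locus
  loci <- loci[vapply(loci, function(l) full(fam$mother_id, l) && full(fam$father_id, l),
                      logical(1))]
  empty <- tibble(locus = character(), null_parent = character(),
                  n_offspring_evidence = integer(), allele = character())
  bind_rows(empty, purrr::map_dfr(loci, function(loc) {
    m <- geno(fam$mother_id, loc); f <- geno(fam$father_id, loc)
    hits <- purrr::map_dfr(fam$offspring$offspring_id, function(o) {
      g <- geno(o, loc)
      if (anyNA(g) || g[1] != g[2]) return(NULL)
      a <- g[1]
      in_f <- a %in% f; in_m <- a %in% m
      if (in_f && !in_m) tibble(null_parent = "mother", allele = a)
      else if (!in_f && in_m) tibble(null_parent = "father", allele = a)
      else NULL
    })
    if (nrow(hits) == 0) return(NULL)
    hits |>
      count(.data$null_parent, .data$allele, name = "n_offspring_evidence") |>
      mutate(locus = loc) |>
      select("locus", "null_parent", "n_offspring_evidence", "allele")
  }))
}

# Phase one locus of one offspring.
# o, m, f: character(2) calls; expected: "L", "R" or "mendelian";
# cls(allele) -> specificity class.
# Returns character(5): status, maternal, paternal, note, flagged_allele.
.phase_locus <- function(o, m, f, expected, cls) {
  res <- function(status, maternal = NA_character_, paternal = NA_character_,
                  note = NA_character_, flagged = NA_character_) {
    c(status, maternal, paternal, note, flagged)
  }
  if (anyNA(o)) return(res("missing"))
  if (anyNA(m) || anyNA(f)) return(res("missing", note = "parent call incomplete"))
  cands <- unique(list(c(o[1], o[2]), c(o[2], o[1])))
  cands <- purrr::keep(cands, ~ .x[1] %in% m && .x[2] %in% f)
  if (length(cands) == 0) {
    return(res("conflict", note = "unattributable: offspring allele absent from parents"))
  }
  if (expected == "mendelian") {
    if (length(cands) == 1) {
      return(res("phased", cands[[1]][1], cands[[1]][2]))
    }
    return(res("ambiguous", note = "multiple Mendelian assignments"))
  }
  own <- if (expected == "L") "l_specific" else "r_specific"
  other <- if (expected == "L") "r_specific" else "l_specific"
  wrong <- function(p) cls(p) == other
  if (length(cands) == 1) {
    p <- cands[[1]][2]
    if (wrong(p)) {
      return(res("conflict",
                 note = sprintf("paternal %s allele in [%s] gamete context",
                                if (other == "r_specific") "R-specific" else "L-specific",
                                expected),
                 flagged = p))
    }
    return(res("phased", cands[[1]][1], cands[[1]][2]))
  }
  keep_cand <- function(cand) {
    p <- cand[2]
    cls(p) == own || (cls(p) == "non_diagnostic" && !(p %in% m))
  }
  kept <- purrr::keep(cands, keep_cand)
  if (length(kept) == 1) {
    return(res("phased", kept[[1]][1], kept[[1]][2]))
  }
  if (length(kept) == 0) {
    wrong_p <- purrr::keep(purrr::map_chr(cands, 2), wrong)
    if (length(wrong_p) > 0) {
      return(res("conflict",
                 note = sprintf("paternal %s allele in [%s] gamete context",
                                if (other == "r_specific") "R-specific" else "L-specific",
                                expected),
                 flagged = wrong_p[1]))
    }
    return(res("ambiguous", note = "paternal origin not determinable"))
  }
  res("ambiguous", note = "multiple assignments consistent with gamete class")
}

#' Phase one offspring against its parents
#'
#' Splits the offspring's diploid genotype into a maternal and a paternal
#' haplotype, locus by locus (see the rules in [phase_family()], which adds
#' the family-level clonal-consensus refinement this standalone call omits).
#'
#' @inheritParams filter_family_loci
#' @param offspring_id Offspring to phase; must belong to `cross_id`.
#' @param loci Loci to phase; defaults to the retained set of
#'   [filter_family_loci()].
#' @param cross_type `"hybrid"` (RL father) or `"control"` (RR father);
#'   inferred from the father's taxon call when `NULL`.
#' @param offspring_taxon Taxon of the offspring; inferred when `NULL`.
#'   Phasing an offspring of unknown taxon in a hybrid cross is an error.
#' @param min_support Passed to [assign_taxa()] for inference.
#' @return Long tibble with columns `individual`, `origin`
#'   (`maternal_R`, `paternal_L` or `paternal_R`), `locus`, `allele`,
#'   `status` (`phased`/`ambiguous`/`conflict`/`missing`), `note`.
#' @export
phase_offspring <- function(offspring_id, cross_id, pedigree, genotypes,
                            registry, loci = NULL, cross_type = NULL,
                            offspring_taxon = NULL, min_support = 2,
                            context = NULL) {
  fam <- .family(pedigree, cross_id)
  if (!offspring_id %in% fam$offspring$offspring_id) {
    abort(sprintf("offspring '%s' not in cross '%s'", offspring_id, cross_id))
  }
  if (is.null(cross_type) || is.null(offspring_taxon)) {
    taxa <- assign_taxa(genotypes, registry, min_support = min_support)
    tax_of <- function(id) {
      t <- taxa$taxon[taxa$individual == id]
      if (length(t) == 0) "unknown" else t
    }
    cross_type <- cross_type %||%
      switch(tax_of(fam$father_id), RL = "hybrid", RR = "control",
             abort("cannot infer cross type: father taxon not RL or RR"))
    offspring_taxon <- offspring_taxon %||% tax_of(offspring_id)
  }
  expected <- if (cross_type == "control") "mendelian"
  else switch(offspring_taxon,
              RL = "L", RR = "R",
              abort(sprintf("offspring '%s' has taxon '%s'; cannot phase in a hybrid cross",
                            offspring_id, offspring_taxon)))
  if (is.null(loci)) {
    filt <- filter_family_loci(cross_id, pedigree, genotypes, registry,
                               context = context)
    loci <- filt$locus[filt$retained]
  }
  geno <- context$geno %||% .geno_env(genotypes)
  lk <- context$lk %||% .allele_class_lookup(registry)
  cls_at <- function(locus) function(a) {
    hit <- lk[paste(locus, a, sep = "\r")]
    if (is.na(hit)) "non_diagnostic" else unname(hit)
  }
  recs <- vapply(loci, function(loc) {
    .phase_locus(geno(offspring_id, loc), geno(fam$mother_id, loc),
                 geno(fam$father_id, loc), expected, cls_at(loc))
  }, character(5))
  rows <- tibble(locus = loci, status = unname(recs[1, ]),
                 maternal = unname(recs[2, ]), paternal = unname(recs[3, ]),
                 note = unname(recs[4, ]), flagged_allele = unname(recs[5, ]))
  .offspring_rows_to_haplotypes(rows, offspring_id, expected)
}

# Expand per-locus phase rows into the two-haplotype long form.
.offspring_rows_to_haplotypes <- function(rows, offspring_id, expected) {
  paternal_origin <- if (expected == "L") "paternal_L" else "paternal_R"
  bind_rows(
    tibble(individual = offspring_id, origin = "maternal_R", locus = rows$locus,
           allele = if_else(rows$status == "phased", rows$maternal, NA_character_),
           status = rows$status, note = rows$note),
    tibble(individual = offspring_id, origin = paternal_origin, locus = rows$locus,
           allele = if_else(rows$status == "phased", rows$paternal, NA_character_),
           status = rows$status, note = rows$note))
}

#' Phase a whole family
#'
#' Runs the full per-family pipeline: locus filtering, null-allele screening,
#' taxon calls, per-offspring phasing, then enforcement of clonal consistency:
#' within one gamete class the paternal haplotype must be identical across
#' offspring, so the father's [L] (and [R]) haplotype is taken as the
#' consensus of paternal alleles, ambiguous loci are re-resolved against it,
#' and deviations become recorded conflicts rather than silent errors — the
#' route by which genome-leakage events surface (see [detect_leakage()]).
#'
#' @inheritParams filter_family_loci
#' @inheritParams phase_offspring
#' @param screen_nulls Drop loci flagged by [screen_null_alleles()].
#' @param loci Optional explicit locus set, bypassing the presence filter
#'   (used for union-scope filtering across families).
#' @return An object of class `phased_family`: a list with elements
#'   `cross_id`, `mother_id`, `father_id`, `cross_type`, `loci` (filter
#'   table), `taxa`, `haplotypes` (long tibble over all offspring),
#'   `father_haplotypes`, `conflicts`, and `params`. Use [tidy()] for the
#'   haplotypes and [glance()] for one-row diagnostics.
#' @export
phase_family <- function(cross_id, pedigree, genotypes, registry,
                         offspring_presence = 0.75, screen_nulls = TRUE,
                         cross_type = NULL, min_support = 2, loci = NULL,
                         context = NULL) {
  fam <- .family(pedigree, cross_id)
  context <- context %||% .phase_context(genotypes, registry, min_support)
  geno <- context$geno
  taxa <- context$taxa
  tax_of <- function(id) {
    t <- taxa$taxon[taxa$individual == id]
    if (length(t) == 0) "unknown" else t
  }
  cross_type <- cross_type %||%
    switch(tax_of(fam$father_id), RL = "hybrid", RR = "control",
           abort(sprintf("cannot infer cross type for '%s': father taxon not RL or RR",
                         cross_id)))

  filt <- filter_family_loci(cross_id, pedigree, genotypes, registry,
                             offspring_presence = offspring_presence,
                             context = context)
  if (!is.null(loci)) {
    filt <- mutate(filt,
                   retained = .data$locus %in% loci &
                     !(.data$reason %in% "parent_missing"),
                   reason = if_else(.data$retained, NA_character_, .data$reason))
  }
  nulls <- if (screen_nulls) {
    screen_null_alleles(cross_id, pedigree, genotypes, registry,
                        loci = filt$locus[filt$retained], context = context)
  } else tibble(locus = character(), null_parent = character(),
                n_offspring_evidence = integer(), allele = character())
  filt <- mutate(filt,
                 reason = if_else(.data$locus %in% nulls$locus, "null_allele", .data$reason),
                 retained = .data$retained & !.data$locus %in% nulls$locus)
  retained <- filt$locus[filt$retained]
  if (length(retained) == 0) abort(sprintf("no loci retained for cross '%s'", cross_id))

  lk <- context$lk
  cls_at <- function(locus) function(a) {
    hit <- lk[paste(locus, a, sep = "\r")]
    if (is.na(hit)) "non_diagnostic" else unname(hit)
  }

  # Within a hybrid cross every offspring arose from either an [L] or an [R]
  # sperm. Since the RR mother contributes no L-specific alleles, the
  # offspring's L-diagnostic locus count measures its paternal gamete's L
  # content directly: an [L] gamete shows L-specific alleles at about all of
  # the father's L-diagnostic loci, an [R] gamete only at rare leaked ones.
  # The boundary at half the father's L-diagnostic loci keeps one or two
  # leaked alleles from flipping the classification — they must surface as
  # locus-level conflicts, not as a different gamete class. This deliberately
  # does not reuse the strict taxon call, which leaves such offspring
  # "unknown".
  father_l_loci <- sum(vapply(registry$locus, function(loc) {
    f <- geno(fam$father_id, loc)
    any(lk[paste(loc, f, sep = "\r")] == "l_specific", na.rm = TRUE)
  }, logical(1)))
  l_needed <- max(min_support, ceiling(father_l_loci / 2))
  gamete_side <- function(id) {
    row <- taxa[taxa$individual == id, ]
    if (nrow(row) == 0) return(NA_character_)
    if (row$n_l_loci >= l_needed) "L"
    else if (row$n_r_loci >= min_support) "R"
    else NA_character_
  }
  offspring <- fam$offspring$offspring_id
  skipped <- character()
  per_off <- purrr::map(setNames(offspring, offspring), function(o) {
    expected <- if (cross_type == "control") "mendelian" else gamete_side(o)
    if (is.na(expected)) {
      skipped <<- c(skipped, o)
      return(NULL)
    }
    recs <- vapply(retained, function(loc) {
      .phase_locus(geno(o, loc), geno(fam$mother_id, loc),
                   geno(fam$father_id, loc), expected, cls_at(loc))
    }, character(5))
    tibble(locus = retained, status = unname(recs[1, ]),
           maternal = unname(recs[2, ]), paternal = unname(recs[3, ]),
           note = unname(recs[4, ]), flagged_allele = unname(recs[5, ]),
           offspring_id = o, expected = expected)
  })
  rows <- bind_rows(per_off)
  if (nrow(rows) == 0) abort(sprintf("no phasable offspring in cross '%s'", cross_id))

  # Consensus paternal haplotypes per gamete class ("must be constant").
  consensus_for <- function(side) {
    sub <- filter(rows, .data$expected == side, .data$status == "phased")
    if (nrow(sub) == 0) return(setNames(character(), character()))
    cons <- sub |>
      count(.data$locus, .data$paternal) |>
      group_by(.data$locus) |>
      filter(.data$n == max(.data$n)) |>
      summarise(allele = if (n() == 1) .data$paternal[1] else NA_character_,
                .groups = "drop")
    setNames(cons$allele, cons$locus)
  }

  if (cross_type == "hybrid") {
    cons_L <- consensus_for("L")
    cons_R <- consensus_for("R")
    # Fill each side from the father's own genotype as the complement of the
    # other side's consensus.
    complement <- function(cons_known) {
      out <- setNames(rep(NA_character_, length(retained)), retained)
      for (loc in retained) {
        f <- geno(fam$father_id, loc)
        if (anyNA(f)) next
        known <- cons_known[loc]
        if (is.na(known)) next
        if (f[1] == known) out[loc] <- f[2]
        else if (f[2] == known) out[loc] <- f[1]
      }
      out[!is.na(out)]
    }
    fill <- function(primary, filler) {
      add <- filler[setdiff(names(filler), names(primary)[!is.na(primary)])]
      primary <- primary[!is.na(primary)]
      c(primary, add[!is.na(add)])
    }
    father_L <- fill(cons_L, complement(cons_R))
    father_R <- fill(cons_R, complement(cons_L))

    lookup_side <- function(tab, loci) unname(tab[loci])
    rows$target <- if_else(rows$expected == "L",
                           lookup_side(father_L, rows$locus),
                           lookup_side(father_R, rows$locus))
    rows$other_side <- if_else(rows$expected == "L",
                               lookup_side(father_R, rows$locus),
                               lookup_side(father_L, rows$locus))

    # Phased loci deviating from the clonal consensus become conflicts.
    dev <- rows$status == "phased" & !is.na(rows$target) &
      rows$paternal != rows$target
    rows$flagged_allele[dev] <- rows$paternal[dev]
    rows$status[dev] <- "conflict"
    rows$note[dev] <- "paternal haplotype inconsistency"
    rows$maternal[dev] <- NA_character_
    rows$paternal[dev] <- NA_character_

    # Ambiguous loci are re-resolved against the consensus haplotype.
    for (i in which(rows$status == "ambiguous" & !is.na(rows$target))) {
      o <- geno(rows$offspring_id[i], rows$locus[i])
      m <- geno(fam$mother_id, rows$locus[i])
      f <- geno(fam$father_id, rows$locus[i])
      cands <- unique(list(c(o[1], o[2]), c(o[2], o[1])))
      cands <- purrr::keep(cands, ~ .x[1] %in% m && .x[2] %in% f)
      hit <- purrr::keep(cands, ~ .x[2] == rows$target[i])
      if (length(hit) == 1) {
        rows$status[i] <- "phased"
        rows$maternal[i] <- hit[[1]][1]
        rows$paternal[i] <- hit[[1]][2]
        rows$note[i] <- NA_character_
      } else if (length(hit) == 0 && length(cands) > 0) {
        ps <- purrr::map_chr(cands, 2)
        rows$status[i] <- "conflict"
        rows$flagged_allele[i] <-
          if (!is.na(rows$other_side[i]) && rows$other_side[i] %in% ps)
            rows$other_side[i] else ps[1]
        rows$note[i] <- "paternal haplotype inconsistency"
      }
    }
    rows$target <- NULL
    rows$other_side <- NULL
  } else {
    father_L <- setNames(character(), character())
    father_R <- consensus_for("mendelian")
  }

  conflicts <- rows |>
    filter(.data$status == "conflict") |>
    mutate(type = if_else(startsWith(.data$note, "paternal haplotype"),
                          "inconsistency",
                          if_else(startsWith(.data$note, "unattributable"),
                                  "unattributable", "cross_genome")),
           expected_genome = if_else(.data$expected == "L", "[L]", "[R]")) |>
    select("offspring_id", "locus", "type", "expected_genome",
           observed_allele = "flagged_allele", description = "note")

  pat_origin <- if_else(rows$expected == "L", "paternal_L", "paternal_R")
  haplotypes <- bind_rows(
    tibble(individual = rows$offspring_id, origin = "maternal_R",
           locus = rows$locus,
           allele = if_else(rows$status == "phased", rows$maternal, NA_character_),
           status = rows$status, note = rows$note),
    tibble(individual = rows$offspring_id, origin = pat_origin,
           locus = rows$locus,
           allele = if_else(rows$status == "phased", rows$paternal, NA_character_),
           status = rows$status, note = rows$note)) |>
    arrange(.data$individual, .data$origin, match(.data$locus, registry$locus))

  father_haplotypes <- bind_rows(
    tibble(origin = "paternal_L", locus = names(father_L), allele = unname(father_L)),
    tibble(origin = "paternal_R", locus = names(father_R), allele = unname(father_R))) |>
    arrange(.data$origin, match(.data$locus, registry$locus))

  structure(list(
    cross_id = cross_id, mother_id = fam$mother_id, father_id = fam$father_id,
    cross_type = cross_type, loci = filt, taxa = taxa,
    haplotypes = haplotypes, father_haplotypes = father_haplotypes,
    conflicts = conflicts, skipped_offspring = skipped,
    params = list(offspring_presence = offspring_presence,
                  screen_nulls = screen_nulls, min_support = min_support)),
    class = "phased_family")
}

#' Phase every family in a pedigree
#'
#' @inheritParams phase_family
#' @param presence_scope `"family"` applies the offspring-presence filter per
#'   family; `"union"` retains, in every family, any locus passing the filter
#'   in at least one family (loci with untyped parents are still skipped
#'   per family).
#' @return Named list of [phase_family()] results, ordered by cross id.
#' @export
phase_families <- function(pedigree, genotypes, registry,
                           offspring_presence = 0.75, screen_nulls = TRUE,
                           min_support = 2,
                           presence_scope = c("family", "union")) {
  presence_scope <- match.arg(presence_scope)
  pedigree <- validate_pedigree(pedigree)
  ids <- sort(unique(pedigree$cross_id))
  context <- .phase_context(genotypes, registry, min_support)
  loci <- NULL
  if (presence_scope == "union") {
    per_family <- purrr::map(ids, filter_family_loci, pedigree = pedigree,
                             genotypes = genotypes, registry = registry,
                             offspring_presence = offspring_presence,
                             context = context)
    loci <- unique(unlist(purrr::map(per_family, ~ .x$locus[.x$retained])))
  }
  purrr::map(setNames(ids, ids), function(id) {
    phase_family(id, pedigree, genotypes, registry,
                 offspring_presence = offspring_presence,
                 screen_nulls = screen_nulls, min_support = min_support,
                 loci = loci, context = context)
  })
}

#' @export
print.phased_family <- function(x, ...) {
  cat(sprintf("<phased_family> cross %s (%s): %s x %s\n", x$cross_id,
              x$cross_type, x$father_id, x$mother_id))
  cat(sprintf("  %d retained loci, %d offspring phased, %d conflicts\n",
              sum(x$loci$retained),
              dplyr::n_distinct(x$haplotypes$individual),
              nrow(x$conflicts)))
  invisible(x)
}

#' Per-offspring taxon and sex calls across a pedigree
#'
#' Convenience join of [assign_taxa()] onto the pedigree, used by the
#' downstream gamete-profile and family-summary steps.
#'
#' @inheritParams filter_family_loci
#' @param min_support Passed to [assign_taxa()].
#' @return Tibble `cross_id`, `father_id`, `mother_id`, `offspring_id`,
#'   `sex`, `taxon`, `father_taxon`.
#' @export
offspring_calls <- function(pedigree, genotypes, registry, min_support = 2) {
  taxa <- assign_taxa(genotypes, registry, min_support = min_support)
  validate_pedigree(pedigree) |>
    left_join(select(taxa, "individual", "taxon"),
              by = c(offspring_id = "individual")) |>
    left_join(select(taxa, "individual", father_taxon = "taxon"),
              by = c(father_id = "individual")) |>
    mutate(taxon = dplyr::coalesce(.data$taxon, "unknown"),
           father_taxon = dplyr::coalesce(.data$father_taxon, "unknown")) |>
    select("cross_id", "father_id", "mother_id", "offspring_id", "sex",
           "taxon", "father_taxon")
}
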