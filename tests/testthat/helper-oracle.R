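# Independent exhaustive-enumeration phasing oracle.
#
# Enumerates every transmission (one allele from the mother x one from the
# father), keeps those reproducing the offspring's unordered genotype, and
# applies the gamete-class rules literally. The implementation under test
# enumerates orderings of the offspring pair instead; the two routes must
# agree locus by locus.

# Memoized (locus, allele) -> specificity class lookup built straight from
# the registry's long allele table.
oracle_cls <- function(registry) {
  tab <- registry_alleles(registry)
  key <- paste(tab$locus, tab$allele)
  function(locus, allele) {
    hit <- tab$class[key == paste(locus, allele)]
    if (length(hit) == 0) "non_diagnostic" else hit
  }
}

oracle_phase_locus <- function(o, m, f, expected, registry, locus,
                               cls_fun = NULL) {
  out <- function(status, maternal = NA_character_, paternal = NA_character_) {
    list(status = status, maternal = maternal, paternal = paternal)
  }
  if (anyNA(o) || anyNA(m) || anyNA(f)) return(out("missing"))
  cands <- list()
  for (mi in m) for (pi in f) {
    if (identical(sort(c(mi, pi)), sort(o))) cands <- c(cands, list(c(mi, pi)))
  }
  cands <- unique(cands)
  if (length(cands) == 0) return(out("conflict"))
  if (expected == "mendelian") {
    if (length(cands) == 1) return(out("phased", cands[[1]][1], cands[[1]][2]))
    return(out("ambiguous"))
  }
  own <- if (expected == "L") "l_specific" else "r_specific"
  other <- if (expected == "L") "r_specific" else "l_specific"
  cls_fun <- cls_fun %||% oracle_cls(registry)
  cls <- function(a) cls_fun(locus, a)
  if (length(cands) == 1) {
    p <- cands[[1]][2]
    if (cls(p) == other) return(out("conflict"))
    return(out("phased", cands[[1]][1], cands[[1]][2]))
  }
  kept <- Filter(function(cand) {
    p <- cand[2]
    cls(p) == own || (cls(p) == "non_diagnostic" && !(p %in% m))
  }, cands)
  if (length(kept) == 1) return(out("phased", kept[[1]][1], kept[[1]][2]))
  if (length(kept) == 0) {
    if (any(vapply(cands, function(cand) cls(cand[2]) == other, logical(1)))) {
      return(out("conflict"))
    }
    return(out("ambiguous"))
  }
  out("ambiguous")
}

# Random small family generator for the oracle property test. Returns the
# genotype table, pedigree, registry and the offspring taxa to phase under.
random_small_family <- function(n_loci = NULL, n_offspring = NULL) {
  n_loci <- n_loci %||% sample(2:10, 1)
  n_offspring <- n_offspring %||% sample(1:6, 1)
  loci <- sprintf("L%02d", seq_len(n_loci))
  # per locus: small universes of L-specific, R-specific and shared alleles
  l_pool <- lapply(seq_len(n_loci), function(i) {
    if (stats::runif(1) < 0.7) as.character(sample(100:119, sample(1:2, 1))) else character()
  })
  r_pool <- lapply(seq_len(n_loci), function(i) {
    if (stats::runif(1) < 0.9) as.character(sample(200:229, sample(1:3, 1))) else character()
  })
  registry <- locus_registry(loci, l_pool, r_pool)
  shared <- lapply(seq_len(n_loci), function(i) as.character(sample(300:309, 3)))
  universe <- lapply(seq_len(n_loci), function(i) {
    unique(c(l_pool[[i]], r_pool[[i]], shared[[i]]))
  })
  draw2 <- function(pool) sample(pool, 2, replace = TRUE)
  inds <- c("DAD", "MOM", sprintf("KID%d", seq_len(n_offspring)))
  rows <- purrr::map_dfr(seq_len(n_loci), function(i) {
    # offspring alleles drawn from the universe (occasionally foreign) so all
    # four statuses get exercised
    geno <- lapply(inds, function(ind) {
      g <- draw2(universe[[i]])
      if (startsWith(ind, "KID") && stats::runif(1) < 0.05) g[1] <- "999"
      if (stats::runif(1) < 0.05) g[sample(1:2, 1)] <- NA
      g
    })
    tibble::tibble(individual = inds, locus = loci[i],
                   allele_1 = vapply(geno, `[`, character(1), 1),
                   allele_2 = vapply(geno, `[`, character(1), 2))
  })
  list(genotypes = genotype_table(rows, registry),
       pedigree = make_pedigree(inds[-(1:2)]),
       registry = registry,
       offspring = inds[-(1:2)])
}
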