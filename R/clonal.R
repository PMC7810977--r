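# Downstream analytics on phased haplotypes: multilocus genotypes, gamete
# profiles, leakage, and the clonal-vs-recombining linkage contrast.

# Haplotype long tibble -> per-haplotype allele matrix over registry loci
# (NA where not phased). Rows keyed by individual + origin.
.hap_matrix <- function(haplotypes, registry) {
  wide <- haplotypes |>
    mutate(allele = if_else(.data$status == "phased", .data$allele, NA_character_)) |>
    distinct(.data$individual, .data$origin, .data$locus, .data$allele) |>
    tidyr::pivot_wider(id_cols = c("individual", "origin"),
                       names_from = "locus", values_from = "allele")
  for (loc in setdiff(registry$locus, names(wide))) wide[[loc]] <- NA_character_
  mat <- as.matrix(wide[, registry$locus, drop = FALSE])
  rownames(mat) <- paste(wide$individual, wide$origin, sep = "\r")
  list(mat = mat, ids = select(wide, "individual", "origin"))
}

#' Canonical multilocus-genotype (MLG) keys
#'
#' One string per haploid genome: its alleles in registry locus order,
#' missing (unphased) positions as `~`, which sorts after alphanumerics so
#' heavily missing keys group last. Two haplotypes have equal keys exactly
#' when their phased allele vectors are equal.
#'
#' @param haplotypes Long haplotype tibble (`individual`, `origin`, `locus`,
#'   `allele`, `status`).
#' @param registry A `hemi_registry` fixing locus order.
#' @return Tibble `individual`, `origin`, `key`, `missing_fraction`.
#' @export
mlg_key <- function(haplotypes, registry) {
  hm <- .hap_matrix(haplotypes, registry)
  keys <- apply(hm$mat, 1, function(r) {
    r[is.na(r)] <- .mlg_missing_token
    paste(r, collapse = ":")
  })
  mutate(hm$ids, key = unname(keys),
         missing_fraction = unname(rowMeans(is.na(hm$mat))))
}

#' Cluster multilocus genotypes, tolerating missing data
#'
#' Filters out variation caused by missing data: haplotypes with more than
#' `max_missing` missing loci are removed; the rest are sorted by missing
#' fraction (most complete first) and greedily merged, each joining the first
#' cluster whose representative it is compatible with (equal wherever both
#' are defined). Representatives fill in from members, so all members of a
#' cluster are pairwise compatible. Compatibility is not transitive; a
#' haplotype compatible with several clusters joins the first and is flagged
#' `ambiguous`.
#'
#' @inheritParams mlg_key
#' @param max_missing Haplotypes with a missing fraction above this are
#'   excluded (default 0.65).
#' @return Object of class `mlg_clustering`: list with `membership`
#'   (tibble `individual`, `origin`, `cluster_id`, `raw_key`,
#'   `missing_fraction`, `ambiguous`), `representatives` (long tibble),
#'   `excluded`, and `clusters` (per-cluster sizes and raw-MLG counts).
#' @export
cluster_mlgs <- function(haplotypes, registry, max_missing = 0.65) {
  keys <- mlg_key(haplotypes, registry)
  hm <- .hap_matrix(haplotypes, registry)
  excluded <- filter(keys, .data$missing_fraction > max_missing)
  kept <- keys |>
    mutate(.row = row_number()) |>
    filter(.data$missing_fraction <= max_missing) |>
    arrange(.data$missing_fraction, .data$individual, .data$origin)
  if (nrow(kept) == 0) abort("all haplotypes exceed the missing-data threshold")

  reps <- list()
  assignment <- integer(nrow(kept))
  ambiguous <- logical(nrow(kept))
  compatible <- function(h, rep) !any(h != rep, na.rm = TRUE)
  for (i in seq_len(nrow(kept))) {
    h <- hm$mat[kept$.row[i], ]
    hits <- which(vapply(reps, compatible, logical(1), h = h))
    if (length(hits) == 0) {
      reps[[length(reps) + 1]] <- h
      assignment[i] <- length(reps)
    } else {
      k <- hits[1]
      assignment[i] <- k
      ambiguous[i] <- length(hits) > 1
      fill <- is.na(reps[[k]]) & !is.na(h)
      reps[[k]][fill] <- h[fill]
    }
  }
  membership <- kept |>
    mutate(cluster_id = assignment, ambiguous = ambiguous) |>
    select("individual", "origin", "cluster_id", raw_key = "key",
           "missing_fraction", "ambiguous")
  representatives <- purrr::imap_dfr(reps, function(r, k) {
    tibble(cluster_id = k, locus = registry$locus, allele = unname(r))
  })
  clusters <- membership |>
    group_by(.data$cluster_id) |>
    summarise(n_members = n(), n_distinct_raw = n_distinct(.data$raw_key),
              .groups = "drop")
  structure(list(membership = membership, representatives = representatives,
                 excluded = select(excluded, "individual", "origin",
                                   "missing_fraction"),
                 clusters = clusters, max_missing = max_missing),
            class = "mlg_clustering")
}

#' @export
print.mlg_clustering <- function(x, ...) {
  cat(sprintf("<mlg_clustering> %d haplotypes -> %d clusters (%d raw MLGs, %d excluded > %.0f%% missing)\n",
              nrow(x$membership), nrow(x$clusters),
              dplyr::n_distinct(x$membership$raw_key), nrow(x$excluded),
              100 * x$max_missing))
  invisible(x)
}

#' Classify each hybrid father's gamete production
#'
#' Offspring taxon is the evidence: an RL offspring of a hybrid father shows
#' [L] sperm, an RR offspring shows [R] sperm; a father producing both is
#' amphispermic. Evidence is pooled over all the father's crosses. Offspring
#' sex is deliberately not used (it is phenotypic); see
#' [summarize_families()] for the sex-concordance report.
#'
#' @param calls Per-offspring tibble with columns `father_id`,
#'   `father_taxon`, `taxon` (e.g. from [offspring_calls()] or
#'   [expand_cross_table()]).
#' @return Tibble per hybrid father: `father_id`, `classes` (`"[L]"`,
#'   `"[R]"` or `"[L],[R]"`), `n_L`, `n_R`, `n_offspring`, `amphispermic`.
#' @export
classify_gamete_profiles <- function(calls) {
  calls |>
    filter(.data$father_taxon == "RL", .data$taxon %in% c("RL", "RR")) |>
    group_by(.data$father_id) |>
    summarise(n_L = sum(.data$taxon == "RL"),
              n_R = sum(.data$taxon == "RR"),
              .groups = "drop") |>
    mutate(n_offspring = .data$n_L + .data$n_R,
           classes = dplyr::case_when(
             .data$n_L > 0 & .data$n_R > 0 ~ "[L],[R]",
             .data$n_L > 0 ~ "[L]",
             TRUE ~ "[R]"),
           amphispermic = .data$n_L > 0 & .data$n_R > 0) |>
    select("father_id", "classes", "n_L", "n_R", "n_offspring", "amphispermic")
}

#' @rdname classify_gamete_profiles
#' @param father_id A single father id; an error if he has no classified
#'   offspring.
#' @export
classify_gamete_profile <- function(father_id, calls) {
  out <- filter(classify_gamete_profiles(calls), .data$father_id == !!father_id)
  if (nrow(out) == 0) {
    abort(sprintf("father '%s' has no classified offspring", father_id))
  }
  out
}

#' Detect genome-leakage events in a phased family
#'
#' Emits one event per (offspring, locus) where the paternal haplotype
#' carries an allele contradicting the gamete's genome of origin: either a
#' species-diagnostic allele of the other species (the direct signature), or
#' a consensus-deviant allele explainable as the father's other-genome
#' allele. Unattributable conflicts (allele absent from both parents) are not
#' leakage and are left in the conflict table.
#'
#' @param phased A [phase_family()] result.
#' @param registry A `hemi_registry`.
#' @return Tibble `offspring_id`, `locus`, `expected_genome`,
#'   `observed_allele`, `observed_class`.
#' @export
detect_leakage <- function(phased, registry) {
  stopifnot(inherits(phased, "phased_family"))
  cf <- phased$conflicts
  if (nrow(cf) == 0) {
    return(tibble(offspring_id = character(), locus = character(),
                  expected_genome = character(), observed_allele = character(),
                  observed_class = character()))
  }
  other_hap <- function(expected_genome) {
    side <- if_else(expected_genome == "[L]", "paternal_R", "paternal_L")
    fh <- phased$father_haplotypes
    purrr::map2_chr(side, cf$locus, function(s, loc) {
      hit <- fh$allele[fh$origin == s & fh$locus == loc]
      if (length(hit) == 1) hit else NA_character_
    })
  }
  cf$other_allele <- other_hap(cf$expected_genome)
  events <- cf |>
    filter(.data$type == "cross_genome" |
             (.data$type == "inconsistency" & !is.na(.data$observed_allele) &
                .data$observed_allele == .data$other_allele))
  events$observed_class <- allele_class(registry, events$locus, events$observed_allele)
  select(events, "offspring_id", "locus", "expected_genome",
         "observed_allele", "observed_class")
}

#' Two-point recombination fractions among a parent's gametes
#'
#' For each locus pair, gametes are classified by their two-locus allele
#' combination; the recombination fraction is the minority phase-pair count
#' over informative gametes, taking the phase pairing that minimises
#' recombinants, so `r` is always in [0, 0.5]. Clonal transmission gives
#' `r = 0` everywhere ("complete linkage"); free recombination gives `r`
#' near 0.5. Only loci heterozygous in the parent are informative when the
#' parent's genotype is supplied.
#'
#' @param gametes Long tibble of haploid genomes: columns `gamete_id` (or
#'   `individual`/`origin`, concatenated), `locus`, `allele`; optionally
#'   `status` (non-`phased` rows are treated as missing).
#' @param parent Optional parent genotype: the parent's rows of a genotype
#'   table; restricts informative loci to those heterozygous in the parent.
#' @param min_gametes Pairs with fewer jointly typed gametes get `NA`.
#' @return Object of class `rf_matrix`: tibble `locus_a`, `locus_b`,
#'   `r_hat`, `n_informative` (upper triangle), with an `as.matrix()` method.
#' @export
two_point_rf <- function(gametes, parent = NULL, min_gametes = 2) {
  g <- as_tibble(gametes)
  if (!"gamete_id" %in% names(g)) {
    g$gamete_id <- paste(g$individual, g$origin, sep = "|")
  }
  if ("status" %in% names(g)) {
    g <- mutate(g, allele = if_else(.data$status == "phased", .data$allele,
                                    NA_character_))
  }
  loci <- unique(g$locus)
  if (!is.null(parent)) {
    het <- parent |>
      filter(!is.na(.data$allele_1), !is.na(.data$allele_2),
             .data$allele_1 != .data$allele_2) |>
      pull("locus")
    loci <- intersect(loci, het)
  }
  if (length(loci) < 2) abort("need at least two informative loci")
  wide <- g |>
    filter(.data$locus %in% loci) |>
    distinct(.data$gamete_id, .data$locus, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = "gamete_id", names_from = "locus",
                       values_from = "allele")
  pairs <- utils::combn(loci, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    a <- wide[[p[1]]]; b <- wide[[p[2]]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < min_gametes) {
      return(tibble(locus_a = p[1], locus_b = p[2], r_hat = NA_real_,
                    n_informative = n))
    }
    ua <- unique(a[ok]); ub <- unique(b[ok])
    if (length(ua) > 2 || length(ub) > 2) {
      # >2 alleles cannot come from one diploid parent
      return(tibble(locus_a = p[1], locus_b = p[2], r_hat = NA_real_,
                    n_informative = n))
    }
    r <- if (length(ua) < 2 || length(ub) < 2) {
      0  # a monomorphic side shows no recombinant class
    } else {
      tab <- table(factor(a[ok], levels = ua), factor(b[ok], levels = ub))
      min(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / n
    }
    tibble(locus_a = p[1], locus_b = p[2], r_hat = r, n_informative = n)
  })
  structure(list(pairs = out, loci = loci), class = "rf_matrix")
}

#' @export
as.matrix.rf_matrix <- function(x, ...) {
  loci <- x$loci
  m <- matrix(NA_real_, length(loci), length(loci), dimnames = list(loci, loci))
  diag(m) <- 0
  for (i in seq_len(nrow(x$pairs))) {
    m[x$pairs$locus_a[i], x$pairs$locus_b[i]] <- x$pairs$r_hat[i]
    m[x$pairs$locus_b[i], x$pairs$locus_a[i]] <- x$pairs$r_hat[i]
  }
  m
}

#' @export
print.rf_matrix <- function(x, ...) {
  cat(sprintf("<rf_matrix> %d loci, %d pairs; r_hat range %.3g-%.3g\n",
              length(x$loci), nrow(x$pairs),
              suppressWarnings(min(x$pairs$r_hat, na.rm = TRUE)),
              suppressWarnings(max(x$pairs$r_hat, na.rm = TRUE))))
  invisible(x)
}

#' Summarise crosses: progeny counts by taxon and sex
#'
#' Tabulates each cross by offspring taxon (RR/RL) and sex, plus dataset
#' totals. Under the XX-XY model with the male-determining factor on the [L]
#' genome, RL offspring should be male and RR offspring female;
#' `n_sex_discordant` counts exceptions per cross without letting sex
#' influence any genetic call.
#'
#' @param calls Per-offspring tibble with `cross_id`, `father_id`, `taxon`,
#'   `sex` (e.g. [offspring_calls()] or [expand_cross_table()] output).
#' @return Object of class `family_summary`: list with `by_cross` (one row
#'   per cross with the six taxon-by-sex cells and `n_sex_discordant`) and
#'   `totals` (one-row tibble: `n_crosses`, `n_offspring`, `rr_daughters`,
#'   `rl_sons`, `sexed_offspring`, `undetermined_offspring`,
#'   `n_sex_discordant`).
#' @export
summarize_families <- function(calls) {
  known <- filter(calls, .data$taxon %in% c("RR", "RL"))
  by_cross <- known |>
    mutate(cell = paste(tolower(.data$taxon), .data$sex, sep = "_")) |>
    count(.data$cross_id, .data$father_id, .data$cell) |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n", values_fill = 0L)
  for (col in c("rr_male", "rr_female", "rr_undetermined",
                "rl_male", "rl_female", "rl_undetermined")) {
    if (!col %in% names(by_cross)) by_cross[[col]] <- 0L
  }
  discord <- known |>
    group_by(.data$cross_id) |>
    summarise(n_sex_discordant = sum((.data$taxon == "RL" & .data$sex == "female") |
                                       (.data$taxon == "RR" & .data$sex == "male")),
              .groups = "drop")
  by_cross <- by_cross |>
    left_join(discord, by = "cross_id") |>
    select("cross_id", "father_id", "rr_male", "rr_female", "rr_undetermined",
           "rl_male", "rl_female", "rl_undetermined", "n_sex_discordant") |>
    arrange(.data$cross_id)
  totals <- tibble(
    n_crosses = dplyr::n_distinct(by_cross$cross_id),
    n_offspring = nrow(known),
    rr_daughters = sum(by_cross$rr_female),
    rl_sons = sum(by_cross$rl_male),
    sexed_offspring = sum(known$sex != "undetermined"),
    undetermined_offspring = sum(known$sex == "undetermined"),
    n_sex_discordant = sum(by_cross$n_sex_discordant))
  structure(list(by_cross = by_cross, totals = totals), class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat(sprintf("<family_summary> %d crosses, %d offspring (%d RR daughters, %d RL sons, %d unsexed)\n",
              x$totals$n_crosses, x$totals$n_offspring, x$totals$rr_daughters,
              x$totals$rl_sons, x$totals$undetermined_offspring))
  invisible(x)
}
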