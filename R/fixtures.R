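#' Packaged example data
#'
#' Small plain-text fixtures shipped with the package:
#' * `waterfrog_loci.csv` — the 15 published microsatellite loci with their
#'   *lessonae*- and *ridibundus*-specific allele lists (sizes in bp).
#' * `waterfrog_crosses.csv` — per-cross progeny counts (taxon by sex) for the
#'   17 experimental hybrid-male crosses, including each father's gamete
#'   classes.
#' * `family60_genotypes_synthetic.csv` / `family60_pedigree_synthetic.csv` —
#'   a constructed single-family dataset emulating the one observed leakage
#'   event: eight RL sons sharing the father's clonal [L] haplotype, one of
#'   which carries the father's R-specific Re1Caga10 allele instead.
#'
#' @param file Fixture file name; `NULL` lists available fixtures.
#' @return Full path to the fixture (or a vector of names).
#' @export
hemiphase_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "hemiphase"))
  } else {
    path <- system.file("extdata", file, package = "hemiphase")
    if (path == "") abort(sprintf("no packaged fixture called '%s'", file))
    path
  }
}

#' The published water-frog locus registry
#'
#' @return A `hemi_registry` of the 15 microsatellite loci.
#' @export
waterfrog_loci <- function() {
  read_locus_registry(hemiphase_example("waterfrog_loci.csv"))
}

#' The published cross table (progeny counts by taxon and sex)
#'
#' @return Tibble with one row per cross: `cross_id`, `father_id`,
#'   `gamete_classes`, and six count columns `rr_male`, `rr_female`,
#'   `rr_undetermined`, `rl_male`, `rl_female`, `rl_undetermined`.
#' @export
waterfrog_crosses <- function() {
  readr::read_csv(hemiphase_example("waterfrog_crosses.csv"),
                  col_types = "ccciiiiii", progress = FALSE)
}

#' Expand a per-cross count table to per-offspring records
#'
#' Turns a cross table shaped like [waterfrog_crosses()] into the long
#' per-offspring form used by [summarize_families()] and
#' [classify_gamete_profiles()], synthesising offspring ids. All fathers in
#' such a table are hybrid (RL) males.
#'
#' @param crosses Tibble shaped like [waterfrog_crosses()].
#' @return Tibble with columns `cross_id`, `father_id`, `mother_id`,
#'   `offspring_id`, `father_taxon`, `taxon`, `sex`.
#' @export
expand_cross_table <- function(crosses) {
  cells <- tidyr::pivot_longer(
    crosses,
    cols = dplyr::matches("^(rr|rl)_(male|female|undetermined)$"),
    names_to = c("taxon", "sex"), names_sep = "_", values_to = "n")
  cells <- filter(cells, .data$n > 0)
  out <- tidyr::uncount(cells, weights = .data$n, .id = "i") |>
    group_by(.data$cross_id) |>
    mutate(offspring_id = sprintf("%s_J%02d", .data$cross_id, row_number())) |>
    ungroup() |>
    mutate(taxon = toupper(.data$taxon),
           mother_id = paste0("F_", .data$cross_id),
           father_taxon = "RL") |>
    select("cross_id", "father_id", "mother_id", "offspring_id",
           "father_taxon", "taxon", "sex")
  out
}
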