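#' Assign taxa from species-diagnostic alleles
#'
#' Each individual is classified from the diagnostic alleles it carries:
#' L-specific *and* R-specific alleles at `min_support` or more loci each give
#' a hybrid (RL) call; diagnostic alleles of only one species give RR or LL;
#' anything less stays `unknown`. Non-diagnostic (shared) alleles never count
#' as evidence. Requiring support at two or more loci guards against a single
#' leaked allele mimicking a hybrid genotype.
#'
#' @param genotypes A genotype table ([genotype_table()]).
#' @param registry A `hemi_registry`.
#' @param min_support Minimum number of diagnostic loci backing any positive
#'   call (default 2).
#' @return Tibble with one row per individual: `individual`, `taxon`
#'   (`"RR"`, `"RL"`, `"LL"` or `"unknown"`), `n_l_loci`, `n_r_loci`,
#'   `ploidy_flag`.
#' @examples
#' reg <- locus_registry(c("A", "B"), list("101", "150"), list("103", c("152", "154")))
#' g <- genotype_table(
#'   data.frame(individual = "x", locus = c("A", "B"),
#'              allele_1 = c("101", "150"), allele_2 = c("103", "152")), reg)
#' assign_taxa(g, reg)
#' @export
assign_taxa <- function(genotypes, registry, min_support = 2) {
  individuals <- unique(genotypes$individual)
  long <- genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    filter(!is.na(.data$allele)) |>
    distinct(.data$individual, .data$locus, .data$allele)
  long$class <- allele_class(registry, long$locus, long$allele)
  support <- long |>
    group_by(.data$individual) |>
    summarise(
      n_l_loci = n_distinct(.data$locus[.data$class == "l_specific"]),
      n_r_loci = n_distinct(.data$locus[.data$class == "r_specific"]),
      .groups = "drop")
  out <- tibble(individual = individuals) |>
    left_join(support, by = "individual") |>
    mutate(across(c("n_l_loci", "n_r_loci"), ~ dplyr::coalesce(.x, 0L)),
           taxon = dplyr::case_when(
             .data$n_l_loci >= min_support & .data$n_r_loci >= min_support ~ "RL",
             .data$n_l_loci == 0 & .data$n_r_loci >= min_support ~ "RR",
             .data$n_r_loci == 0 & .data$n_l_loci >= min_support ~ "LL",
             TRUE ~ "unknown"))
  left_join(out, assess_ploidy(genotypes), by = "individual") |>
    select("individual", "taxon", "n_l_loci", "n_r_loci", "ploidy_flag")
}

#' @rdname assign_taxa
#' @param individual A single individual id present in `genotypes`.
#' @export
assign_taxon <- function(individual, genotypes, registry, min_support = 2) {
  if (!individual %in% genotypes$individual) {
    abort(sprintf("individual '%s' not in genotype table", individual))
  }
  filter(assign_taxa(genotypes, registry, min_support = min_support),
         .data$individual == !!individual)
}

#' Allele-count ploidy screen
#'
#' Diploid-consistent individuals show at most two alleles per locus. More
#' than two (possible only when the genotype table was read permissively)
#' flags a possible polyploid; fewer than three typed loci is insufficient
#' evidence either way. Peak-intensity dosage evidence is outside the data
#' model.
#'
#' @param genotypes A genotype table.
#' @return Tibble `individual`, `ploidy_flag` in
#'   `c("diploid_consistent", "possible_polyploid", "insufficient")`.
#' @export
assess_ploidy <- function(genotypes) {
  genotypes |>
    group_by(.data$individual) |>
    summarise(n_typed = sum(.data$n_alleles > 0),
              max_alleles = max(c(0L, .data$n_alleles)),
              .groups = "drop") |>
    mutate(ploidy_flag = dplyr::case_when(
      .data$max_alleles > 2 ~ "possible_polyploid",
      .data$n_typed < 3 ~ "insufficient",
      TRUE ~ "diploid_consistent")) |>
    select("individual", "ploidy_flag")
}

#' Count diagnostic alleles
#'
#' In `"registry"` mode, tallies the distinct (locus, allele) entries the
#' registry declares per specificity class. In `"observed"` mode, tallies the
#' distinct (locus, allele) pairs actually seen in a genotype table, with
#' `n_total` also counting non-diagnostic alleles.
#'
#' @param x A genotype table (`"observed"` mode) or a `hemi_registry`
#'   (`"registry"` mode, auto-detected).
#' @param registry Registry used to classify observed alleles.
#' @param mode `"observed"` or `"registry"`.
#' @return One-row tibble: `n_total`, `n_l_specific`, `n_r_specific`.
#' @export
count_diagnostic_alleles <- function(x, registry = NULL,
                                     mode = c("observed", "registry")) {
  if (inherits(x, "hemi_registry")) mode <- "registry" else mode <- match.arg(mode)
  if (mode == "registry") {
    reg <- if (inherits(x, "hemi_registry")) x else registry
    diag <- registry_alleles(reg)
    return(tibble(n_total = nrow(diag),
                  n_l_specific = sum(diag$class == "l_specific"),
                  n_r_specific = sum(diag$class == "r_specific")))
  }
  if (is.null(registry)) abort("observed mode needs a registry")
  seen <- x |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    filter(!is.na(.data$allele)) |>
    distinct(.data$locus, .data$allele)
  cls <- allele_class(registry, seen$locus, seen$allele)
  tibble(n_total = nrow(seen),
         n_l_specific = sum(cls == "l_specific"),
         n_r_specific = sum(cls == "r_specific"))
}
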