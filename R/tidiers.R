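#' Tidy and glance methods for hemiphase result objects
#'
#' `tidy()` returns the long per-unit table of a result; `glance()` a one-row
#' summary, in the broom convention.
#'
#' @param x A `phased_family`, `mlg_clustering`, `rf_matrix` or
#'   `family_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @name hemiphase-tidiers
NULL

#' @rdname hemiphase-tidiers
#' @method tidy phased_family
#' @export
tidy.phased_family <- function(x, ...) {
  mutate(x$haplotypes, cross_id = x$cross_id, .before = 1)
}

#' @rdname hemiphase-tidiers
#' @method glance phased_family
#' @export
glance.phased_family <- function(x, ...) {
  st <- x$haplotypes$status
  tibble(cross_id = x$cross_id, cross_type = x$cross_type,
         father_id = x$father_id, mother_id = x$mother_id,
         n_offspring = dplyr::n_distinct(x$haplotypes$individual),
         n_skipped = length(x$skipped_offspring),
         n_retained_loci = sum(x$loci$retained),
         n_dropped_null = sum(x$loci$reason %in% "null_allele"),
         prop_phased = mean(st == "phased"),
         n_ambiguous = sum(st == "ambiguous") / 2L,
         n_conflicts = nrow(x$conflicts))
}

#' @rdname hemiphase-tidiers
#' @method tidy mlg_clustering
#' @export
tidy.mlg_clustering <- function(x, ...) x$membership

#' @rdname hemiphase-tidiers
#' @method glance mlg_clustering
#' @export
glance.mlg_clustering <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$membership),
         n_clusters = nrow(x$clusters),
         n_raw_mlgs = dplyr::n_distinct(x$membership$raw_key),
         n_excluded = nrow(x$excluded),
         n_ambiguous = sum(x$membership$ambiguous),
         max_missing = x$max_missing)
}

#' @rdname hemiphase-tidiers
#' @method tidy rf_matrix
#' @export
tidy.rf_matrix <- function(x, ...) x$pairs

#' @rdname hemiphase-tidiers
#' @method glance rf_matrix
#' @export
glance.rf_matrix <- function(x, ...) {
  r <- x$pairs$r_hat
  tibble(n_loci = length(x$loci), n_pairs = nrow(x$pairs),
         n_estimated = sum(!is.na(r)),
         mean_rf = mean(r, na.rm = TRUE),
         max_rf = if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE),
         prop_linked = mean(r == 0, na.rm = TRUE))
}

#' @rdname hemiphase-tidiers
#' @method tidy family_summary
#' @export
tidy.family_summary <- function(x, ...) x$by_cross

#' @rdname hemiphase-tidiers
#' @method glance family_summary
#' @export
glance.family_summary <- function(x, ...) x$totals
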