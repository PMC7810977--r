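#' Run the full analysis pipeline and write reports
#'
#' Wires the stages together: taxon assignment, family-wise phasing,
#' MLG clustering of the paternal haplotypes, gamete-profile classification,
#' leakage detection, per-parent two-point linkage, and the family summary.
#' All outputs are plain TSV plus a JSON run manifest recording inputs,
#' parameters and package version; a rerun with identical inputs and
#' parameters reproduces every file byte for byte. Inputs are never
#' modified.
#'
#' @param genotypes Genotype table ([read_genotypes()] / [genotype_table()]).
#' @param registry A `hemi_registry`.
#' @param pedigree Pedigree tibble ([read_pedigree()]).
#' @param out_dir Output directory (created if needed); reports:
#'   `taxon_calls.tsv`, `phased.tsv`, `mlg_clusters.tsv`,
#'   `gamete_profiles.tsv`, `leakage_events.tsv`, `rf_matrix.tsv`,
#'   `family_summary.tsv`, `manifest.json`.
#' @param offspring_presence,min_support,max_missing,screen_nulls,presence_scope
#'   Stage parameters, echoed in the manifest.
#' @param inputs Optional named list of input file paths for the manifest.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(genotypes, registry, pedigree, out_dir,
                         offspring_presence = 0.75, min_support = 2,
                         max_missing = 0.65, screen_nulls = TRUE,
                         presence_scope = "family", inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  tsv <- function(df, f) readr::write_tsv(df, path(f), na = "")

  taxa <- assign_taxa(genotypes, registry, min_support = min_support)
  tsv(taxa, "taxon_calls.tsv")

  phased <- phase_families(pedigree, genotypes, registry,
                           offspring_presence = offspring_presence,
                           screen_nulls = screen_nulls,
                           min_support = min_support,
                           presence_scope = presence_scope)
  haplotypes <- bind_rows(purrr::map(phased, tidy))
  write_phased(select(haplotypes, -"cross_id"), path("phased.tsv"),
               registry = registry)

  clust <- cluster_mlgs(
    filter(haplotypes, .data$origin %in% c("paternal_L", "paternal_R")),
    registry, max_missing = max_missing)
  tsv(tidy(clust), "mlg_clusters.tsv")

  calls <- offspring_calls(pedigree, genotypes, registry,
                           min_support = min_support)
  profiles <- classify_gamete_profiles(calls)
  tsv(profiles, "gamete_profiles.tsv")

  leakage <- purrr::map_dfr(phased, function(pf) {
    ev <- detect_leakage(pf, registry)
    if (nrow(ev)) mutate(ev, cross_id = pf$cross_id, .before = 1) else NULL
  })
  if (nrow(leakage) == 0) {
    leakage <- tibble(cross_id = character(), offspring_id = character(),
                      locus = character(), expected_genome = character(),
                      observed_allele = character(), observed_class = character())
  }
  tsv(leakage, "leakage_events.tsv")

  rf <- purrr::map_dfr(sort(unique(pedigree$father_id)), function(fid) {
    gam <- filter(haplotypes,
                  .data$origin %in% c("paternal_L", "paternal_R"),
                  .data$individual %in%
                    pedigree$offspring_id[pedigree$father_id == fid])
    gam <- mutate(gam, gamete_id = paste(.data$individual, .data$origin, sep = "|"))
    if (dplyr::n_distinct(gam$gamete_id) < 2) return(NULL)
    parent <- filter(genotypes, .data$individual == fid)
    res <- tryCatch(two_point_rf(gam, parent = parent), error = function(e) NULL)
    if (is.null(res)) NULL else mutate(tidy(res), parent_id = fid, .before = 1)
  })
  if (nrow(rf) == 0) {
    rf <- tibble(parent_id = character(), locus_a = character(),
                 locus_b = character(), r_hat = double(),
                 n_informative = integer())
  }
  tsv(rf, "rf_matrix.tsv")

  fs <- summarize_families(calls)
  tsv(tidy(fs), "family_summary.tsv")

  manifest <- list(
    package = "hemiphase",
    version = as.character(utils::packageVersion("hemiphase")),
    inputs = inputs %||% list(genotypes = "in-memory", registry = "in-memory",
                              pedigree = "in-memory"),
    parameters = list(offspring_presence = offspring_presence,
                      min_support = min_support, max_missing = max_missing,
                      screen_nulls = screen_nulls,
                      presence_scope = presence_scope),
    outputs = c("taxon_calls.tsv", "phased.tsv", "mlg_clusters.tsv",
                "gamete_profiles.tsv", "leakage_events.tsv", "rf_matrix.tsv",
                "family_summary.tsv"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(taxa = taxa, phased = phased, haplotypes = haplotypes,
                 clusters = clust, profiles = profiles, leakage = leakage,
                 rf = rf, summary = fs, manifest = manifest))
}
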