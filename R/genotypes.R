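#' Build a genotype table from per-call records
#'
#' The genotype table is the package's central container: one row per
#' (individual, locus) call, with the unordered diploid allele pair stored in
#' sorted columns `allele_1`/`allele_2`. Missing data is explicit: a call with
#' both alleles `NA` is missing; a half-call (one observed allele) keeps the
#' second slot `NA` and is treated as missing for phasing but present for
#' multilocus-genotype comparison.
#'
#' @param df Data frame with columns `individual`, `locus`, `allele_1`,
#'   `allele_2` (extra rows per call are merged; blank/`-` tokens become `NA`).
#' @param registry A `hemi_registry`; all loci in `df` must be listed in it.
#' @param permissive If `TRUE`, calls with more than two distinct alleles are
#'   kept (first two retained, the full count in `n_alleles`) instead of
#'   raising a possible-triploidy error.
#' @param marker_mode `"microsatellite"` or `"snp"`.
#' @return Tibble with columns `individual`, `locus`, `allele_1`, `allele_2`,
#'   `n_alleles`, carrying a `marker_mode` attribute.
#' @export
genotype_table <- function(df, registry, permissive = FALSE,
                           marker_mode = c("microsatellite", "snp")) {
  marker_mode <- match.arg(marker_mode)
  df <- as_tibble(df)
  names(df)[1:4] <- c("individual", "locus", "allele_1", "allele_2")
  df <- mutate(df,
               individual = as.character(.data$individual),
               locus = as.character(.data$locus),
               allele_1 = .norm_token(.data$allele_1),
               allele_2 = .norm_token(.data$allele_2))
  .check_allele_tokens(c(df$allele_1, df$allele_2))
  unknown <- setdiff(unique(df$locus), registry$locus)
  if (length(unknown) > 0) {
    abort(sprintf("locus absent from registry: %s", paste(unknown, collapse = ", ")))
  }
  # Fast path: one row per (individual, locus) call.
  if (!anyDuplicated(paste(df$individual, df$locus, sep = "\r"))) {
    a1 <- df$allele_1; a2 <- df$allele_2
    # order the pair (numeric-aware where both parse as numbers)
    n1 <- suppressWarnings(as.numeric(a1)); n2 <- suppressWarnings(as.numeric(a2))
    swap <- !is.na(a1) & !is.na(a2) &
      if_else(!is.na(n1) & !is.na(n2), n1 > n2, a1 > a2)
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    one_sided <- is.na(a1) & !is.na(a2)
    a1[one_sided] <- a2[one_sided]; a2[one_sided] <- NA_character_
    out <- tibble(individual = df$individual, locus = df$locus,
                  allele_1 = a1, allele_2 = a2,
                  n_alleles = if_else(is.na(a1), 0L,
                                      if_else(is.na(a2) | a1 == a2, 1L, 2L))) |>
      arrange(.data$individual, match(.data$locus, registry$locus))
    attr(out, "marker_mode") <- marker_mode
    return(out)
  }

  # Merge duplicate rows for one (individual, locus): identical rows collapse,
  # complementary rows union. A homozygote needs some row showing the allele in
  # both slots; a single observed slot stays a half-call.
  merged <- df |>
    mutate(n_slots = (!is.na(.data$allele_1)) + (!is.na(.data$allele_2)),
           hom_row = !is.na(.data$allele_1) & !is.na(.data$allele_2) &
             .data$allele_1 == .data$allele_2) |>
    group_by(.data$individual, .data$locus) |>
    summarise(alleles = list(unique(c(.data$allele_1, .data$allele_2)[
      !is.na(c(.data$allele_1, .data$allele_2))])),
      any_hom_row = any(.data$hom_row),
      .groups = "drop")
  build_call <- function(alleles, any_hom_row) {
    k <- length(alleles)
    if (k > 2 && !permissive) {
      abort(sprintf(">2 distinct alleles in a diploid call (possible triploidy): %s",
                    paste(alleles, collapse = "/")))
    }
    a <- .sort_alleles(alleles)
    if (k == 0) c(NA_character_, NA_character_, "0")
    else if (k == 1 && !any_hom_row) c(a, NA_character_, "1")  # half-call
    else if (k == 1) c(a, a, "1")                              # homozygote
    else c(a[1], a[2], as.character(k))
  }
  calls <- purrr::map2(merged$alleles, merged$any_hom_row, build_call)
  out <- tibble(individual = merged$individual,
                locus = merged$locus,
                allele_1 = vapply(calls, `[`, character(1), 1),
                allele_2 = vapply(calls, `[`, character(1), 2),
                n_alleles = as.integer(vapply(calls, `[`, character(1), 3))) |>
    arrange(.data$individual, match(.data$locus, registry$locus))
  attr(out, "marker_mode") <- marker_mode
  out
}

#' @rdname genotype_table
#' @param x A genotype table.
#' @export
marker_mode <- function(x) attr(x, "marker_mode") %||% "microsatellite"

#' Read a long-format genotype file
#'
#' Expects columns individual, locus, allele1, allele2 (allele2 may repeat
#' allele1 for homozygotes; blank or `-` means missing). Rows may appear in
#' any order; duplicated identical rows are merged.
#'
#' @inheritParams genotype_table
#' @param path File path (CSV/TSV).
#' @param delim Optional explicit delimiter.
#' @return A genotype table, see [genotype_table()].
#' @export
read_genotypes <- function(path, registry, permissive = FALSE, delim = NULL,
                           marker_mode = c("microsatellite", "snp")) {
  raw <- .read_delim(path, delim)
  if (ncol(raw) < 4) abort("genotype file needs columns: individual, locus, allele1, allele2")
  genotype_table(raw[, 1:4], registry, permissive = permissive,
                 marker_mode = match.arg(marker_mode))
}

#' Write a genotype table
#'
#' @param genotypes A genotype table.
#' @param path Output path.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, delim = NULL) {
  readr::write_delim(select(genotypes, "individual", "locus", "allele_1", "allele_2"),
                     path, delim = .guess_delim(path, delim), na = "")
  invisible(path)
}

#' Read a pedigree / family map
#'
#' One row per offspring: cross_id, mother_id, father_id, offspring_id and
#' optionally sex (`male`/`female`/`undetermined`). The same father may sire
#' several crosses; an offspring may belong to exactly one.
#'
#' @param path File path (CSV/TSV).
#' @param delim Optional explicit delimiter.
#' @return Tibble with columns `cross_id`, `mother_id`, `father_id`,
#'   `offspring_id`, `sex`.
#' @export
read_pedigree <- function(path, delim = NULL) {
  raw <- .read_delim(path, delim)
  if (ncol(raw) < 4) abort("pedigree needs columns: cross_id, mother_id, father_id, offspring_id[, sex]")
  ped <- tibble(cross_id = .norm_token(raw[[1]]),
                mother_id = .norm_token(raw[[2]]),
                father_id = .norm_token(raw[[3]]),
                offspring_id = .norm_token(raw[[4]]),
                sex = if (ncol(raw) >= 5) .norm_token(raw[[5]]) else NA_character_)
  ped$sex[is.na(ped$sex)] <- "undetermined"
  bad_sex <- setdiff(unique(ped$sex), c("male", "female", "undetermined"))
  if (length(bad_sex) > 0) abort(sprintf("unknown sex value(s): %s", paste(bad_sex, collapse = ", ")))
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks the family invariants: parents present, mother distinct from
#' father, each offspring in exactly one cross.
#'
#' @param ped Pedigree tibble (see [read_pedigree()]).
#' @return The validated tibble.
#' @export
validate_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  if (!"sex" %in% names(ped)) ped$sex <- "undetermined"
  if (anyNA(ped$mother_id) || anyNA(ped$father_id)) abort("missing parent id in pedigree")
  if (any(ped$mother_id == ped$father_id)) abort("mother and father identical in a cross")
  dup <- ped |>
    distinct(.data$cross_id, .data$offspring_id) |>
    count(.data$offspring_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("offspring listed in more than one family: %s",
                  paste(dup$offspring_id, collapse = ", ")))
  }
  multi_parent <- ped |>
    distinct(.data$cross_id, .data$mother_id, .data$father_id) |>
    count(.data$cross_id) |>
    filter(n > 1)
  if (nrow(multi_parent) > 0) {
    abort(sprintf("cross with conflicting parent ids: %s",
                  paste(multi_parent$cross_id, collapse = ", ")))
  }
  ped
}

#' Write a pedigree table
#'
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, delim = NULL) {
  readr::write_delim(select(ped, "cross_id", "mother_id", "father_id",
                            "offspring_id", "sex"),
                     path, delim = .guess_delim(path, delim), na = "")
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' GT-only, biallelic-only: multiallelic records are skipped (with a count
#' reported in the `n_skipped` attribute) or rejected. Alleles are stored as
#' REF/ALT base symbols; `./.` becomes a missing call and half-calls such as
#' `0/.` keep one allele.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param sample_ids Optional subset of samples; all by default. Requesting a
#'   sample absent from the header is an error.
#' @param skip_multiallelic If `TRUE` (default) drop records with >1 ALT
#'   allele, else raise an error on them.
#' @return A genotype table in SNP mode with loci named `CHROM:POS` (or the
#'   VCF ID when present), plus attributes `n_skipped` and `registry` (a
#'   [snp_registry()] over the retained sites).
#' @export
read_snp_vcf <- function(path, sample_ids = NULL, skip_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  if (is.null(sample_ids)) sample_ids <- samples
  missing_samples <- setdiff(sample_ids, samples)
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) absent from VCF header: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  multi <- grepl(",", fix$ALT %||% "", fixed = TRUE)
  if (any(multi) && !skip_multiallelic) abort("multiallelic record(s) in VCF")
  keep <- !multi
  loci <- ifelse(!is.na(fix$ID) & fix$ID != ".", fix$ID,
                 paste0(fix$CHROM, ":", fix$POS))
  calls <- purrr::map_dfr(which(keep), function(i) {
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    code_to_allele <- function(code) {
      dplyr::case_match(code, "0" ~ ref, "1" ~ alt, .default = NA_character_)
    }
    g <- gt[i, sample_ids]
    parts <- stringr::str_split_fixed(ifelse(is.na(g), "./.", g), "[/|]", 2)
    tibble(individual = sample_ids, locus = loci[i],
           allele_1 = code_to_allele(parts[, 1]),
           allele_2 = code_to_allele(parts[, 2]))
  })
  reg <- snp_registry(loci[keep])
  out <- genotype_table(calls, reg, marker_mode = "snp")
  attr(out, "n_skipped") <- sum(multi)
  attr(out, "registry") <- reg
  out
}

#' Write phased haplotypes to a long-format table
#'
#' One row per (individual, origin, locus); alleles only where status is
#' `phased`. Rows are sorted by individual, origin, and registry locus order
#' so output is reproducible; [read_phased()] round-trips exactly.
#'
#' @param haplotypes Long haplotype tibble with columns `individual`,
#'   `origin`, `locus`, `allele`, `status`.
#' @param path Output path (TSV by default).
#' @param registry Optional `hemi_registry` fixing the locus sort order.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_phased <- function(haplotypes, path, registry = NULL, delim = NULL) {
  if (nrow(haplotypes) == 0) abort("no haplotypes to write")
  locus_order <- registry$locus %||% unique(haplotypes$locus)
  out <- haplotypes |>
    select("individual", "origin", "locus", "allele", "status") |>
    arrange(.data$individual, .data$origin, match(.data$locus, locus_order))
  readr::write_delim(out, path, delim = .guess_delim(path, delim %||% "\t"), na = "")
  invisible(path)
}

#' @rdname write_phased
#' @export
read_phased <- function(path, delim = NULL) {
  raw <- .read_delim(path, delim %||% "\t")
  tibble(individual = raw$individual, origin = raw$origin, locus = raw$locus,
         allele = .norm_token(raw$allele), status = raw$status)
}
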