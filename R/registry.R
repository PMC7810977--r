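#' Construct a locus registry of species-diagnostic alleles
#'
#' A locus registry records, for every marker, which alleles are diagnostic
#' for the *P. lessonae* (L) genome and which for the *P. ridibundus* (R)
#' genome. Alleles listed for neither side are non-diagnostic (shared between
#' species). Row order is meaningful: it defines the canonical locus order
#' used in multilocus-genotype strings and all tabular outputs.
#'
#' @param locus Character vector of unique locus names.
#' @param l_alleles,r_alleles Lists of character vectors (one per locus) of
#'   L-specific and R-specific allele tokens. Microsatellite alleles are
#'   fragment lengths in base pairs (stored as strings); SNP alleles are base
#'   symbols.
#' @return A tibble of class `hemi_registry` with columns `locus`,
#'   `l_alleles`, `r_alleles` (list-columns).
#' @examples
#' locus_registry("Res20", list("124"), list(character()))
#' @export
locus_registry <- function(locus, l_alleles, r_alleles) {
  locus <- as.character(locus)
  if (length(locus) == 0) abort("a registry needs at least one locus")
  if (anyDuplicated(locus)) {
    abort(sprintf("duplicate locus name(s): %s",
                  paste(unique(locus[duplicated(locus)]), collapse = ", ")))
  }
  norm <- function(l) lapply(l, function(x) {
    x <- .norm_token(as.character(x))
    x <- x[!is.na(x)]
    .check_allele_tokens(x)
    unique(x)
  })
  l_alleles <- norm(l_alleles)
  r_alleles <- norm(r_alleles)
  stopifnot(length(l_alleles) == length(locus),
            length(r_alleles) == length(locus))
  both <- purrr::map2(l_alleles, r_alleles, intersect)
  offending <- lengths(both) > 0
  if (any(offending)) {
    abort(sprintf(
      "allele(s) listed as both L- and R-specific at locus %s: %s",
      paste(locus[offending], collapse = ", "),
      paste(unlist(both[offending]), collapse = ", ")))
  }
  out <- tibble(locus = locus, l_alleles = l_alleles, r_alleles = r_alleles)
  class(out) <- c("hemi_registry", class(out))
  out
}

#' Read a locus registry from a delimited file
#'
#' Expects columns locus, L-specific alleles, R-specific alleles (by name if
#' recognisable, else by position), with multiple alleles separated by `/` and
#' `-`/`–` or an empty field meaning none.
#'
#' @param path File path (CSV or TSV; delimiter guessed from the extension).
#' @param delim Optional explicit field delimiter.
#' @return A [locus_registry()] tibble, preserving file row order.
#' @export
read_locus_registry <- function(path, delim = NULL) {
  raw <- .read_delim(path, delim)
  if (ncol(raw) < 3) abort("registry file needs 3 columns: locus, L alleles, R alleles")
  nm <- tolower(names(raw))
  loccol <- which(grepl("locus|marker", nm))[1]
  lcol <- which(grepl("lesson|l_spec|l_allele", nm))[1]
  rcol <- which(grepl("ridib|r_spec|r_allele", nm))[1]
  if (is.na(loccol)) loccol <- 1L
  if (is.na(lcol)) lcol <- 2L
  if (is.na(rcol)) rcol <- 3L
  split_alleles <- function(x) {
    x <- .norm_token(x)
    lapply(x, function(v) {
      if (is.na(v)) character() else .norm_token(strsplit(v, "/", fixed = TRUE)[[1]])
    })
  }
  locus_registry(raw[[loccol]],
                 split_alleles(raw[[lcol]]),
                 split_alleles(raw[[rcol]]))
}

#' Write a locus registry to a delimited file
#'
#' Inverse of [read_locus_registry()]; `read(write(x))` reproduces `x`.
#'
#' @param registry A `hemi_registry`.
#' @param path Output path (extension selects the delimiter).
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_locus_registry <- function(registry, path, delim = NULL) {
  fmt <- function(l) vapply(l, function(x) {
    if (length(x) == 0) "-" else paste(x, collapse = "/")
  }, character(1))
  out <- tibble(locus = registry$locus,
                lessonae_alleles = fmt(registry$l_alleles),
                ridibundus_alleles = fmt(registry$r_alleles))
  readr::write_delim(out, path, delim = .guess_delim(path, delim))
  invisible(path)
}

#' Long view of a registry's diagnostic alleles
#'
#' @param registry A `hemi_registry`.
#' @return Tibble with columns `locus`, `allele`,
#'   `class` (`"l_specific"`/`"r_specific"`).
#' @export
registry_alleles <- function(registry) {
  bind_rows(
    tidyr::unnest(select(tibble::as_tibble(registry), "locus", allele = "l_alleles"),
                  "allele") |> mutate(class = "l_specific"),
    tidyr::unnest(select(tibble::as_tibble(registry), "locus", allele = "r_alleles"),
                  "allele") |> mutate(class = "r_specific")
  )
}

# Fast (locus, allele) -> class lookup used throughout phasing.
.allele_class_lookup <- function(registry) {
  diag <- registry_alleles(registry)
  setNames(diag$class, paste(diag$locus, diag$allele, sep = "\r"))
}

#' Classify alleles as L-specific, R-specific or non-diagnostic
#'
#' @param registry A `hemi_registry`.
#' @param locus,allele Parallel vectors.
#' @return Character vector in
#'   `c("l_specific", "r_specific", "non_diagnostic")`; `NA` for missing
#'   alleles.
#' @export
allele_class <- function(registry, locus, allele) {
  lk <- .allele_class_lookup(registry)
  out <- unname(lk[paste(locus, allele, sep = "\r")])
  out[is.na(out) & !is.na(allele)] <- "non_diagnostic"
  out
}

#' Build a registry for SNP loci
#'
#' SNP registries usually start with no diagnostic assignments (every allele
#' non-diagnostic); segregation patterns alone then drive phasing. Diagnostic
#' base symbols can be supplied per locus when known.
#'
#' @param loci Character vector of locus names (e.g. `"chr1:1234"`).
#' @param l_alleles,r_alleles Optional named lists (locus -> character vector)
#'   of diagnostic base symbols.
#' @return A `hemi_registry`.
#' @export
snp_registry <- function(loci, l_alleles = list(), r_alleles = list()) {
  pick <- function(named, loc) if (loc %in% names(named)) named[[loc]] else character()
  locus_registry(loci,
                 lapply(loci, pick, named = l_alleles),
                 lapply(loci, pick, named = r_alleles))
}
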