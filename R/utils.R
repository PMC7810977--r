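# Internal helpers shared across modules.

# Tokens treated as "no value" in delimited inputs. The en-dash appears in
# published allele tables.
.na_tokens <- c("", "-", "–", "NA", "na", ".", "./.")

.norm_token <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[x %in% .na_tokens] <- NA_character_
  x
}

# Allele tokens are opaque strings (fragment lengths in bp for
# microsatellites, base symbols for SNPs); one validation for both.
.check_allele_tokens <- function(x, context = "allele") {
  bad <- x[!is.na(x) & !grepl("^[A-Za-z0-9_.]+$", x)]
  if (length(bad) > 0) {
    abort(sprintf("unparsable %s token(s): %s", context,
                  paste(unique(bad), collapse = ", ")))
  }
  invisible(x)
}

# Delimiter from file extension, overridable.
.guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

.read_delim <- function(path, delim = NULL) {
  readr::read_delim(path, delim = .guess_delim(path, delim),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE, na = character())
}

# Deterministic 31-bit string hash used to derive per-family RNG substreams
# from the global seed, so simulated families are independent of the order in
# which crosses are generated. Always < 2^31.
stable_hash <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "|"))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483629
  as.integer(h)
}

# Order alleles within an unordered diploid call: numeric-aware so that
# microsatellite fragment lengths sort as numbers, SNP bases lexically.
.sort_alleles <- function(x) stringr::str_sort(x, numeric = TRUE)

# Sentinel used in canonical MLG strings; sorts after alphanumerics in the C
# locale so all-missing keys group last.
.mlg_missing_token <- "~"
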