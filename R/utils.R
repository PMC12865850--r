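#' Normalize a drug name for cross-database matching
#'
#' Lowercases and strips whitespace and punctuation. Deliberately exact:
#' no fuzzy matching, so the mapping is reproducible and auditable. A
#' synonym table can be applied afterwards via \code{synonyms}.
#'
#' @param x Character vector of raw drug names.
#' @param synonyms Optional named character vector mapping normalized names
#'   to replacement normalized names.
#' @return Character vector of normalized names. Idempotent:
#'   \code{normalizeDrugName(normalizeDrugName(x))} equals
#'   \code{normalizeDrugName(x)}.
#' @export
#' @examples
#' normalizeDrugName(c("Aspirin ", "5-Fluoro Uracil"))
normalizeDrugName <- function(x, synonyms = NULL) {
  out <- gsub("[[:space:][:punct:]]+", "", tolower(as.character(x)))
  if (!is.null(synonyms)) {
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

#' Canonical unordered pair key
#'
#' Orders the two (normalized) identifiers lexicographically and joins them,
#' so that (A,B) and (B,A) yield the identical key.
#'
#' @param a,b Character vectors of equal length.
#' @return Character vector of keys of the form \code{"x||y"} with
#'   \code{x <= y}.
#' @export
#' @examples
#' pairKey("b", "a") == pairKey("a", "b")
pairKey <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "||")
}

# Split a pair key back into its two members.
splitPairKey <- function(key) {
  parts <- strsplit(key, "||", fixed = TRUE)
  data.frame(drug_a = vapply(parts, `[`, "", 1L),
             drug_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Ordered factor on the shared severity scale.
toxicityFactor <- function(x) {
  factor(x, levels = toxicityLevels(), ordered = TRUE)
}

# Strip isoform suffixes ("P12345-2" -> "P12345"); configurable at call sites.
stripIsoform <- function(ids) sub("-.*$", "", ids)

# Run code under a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic TSV writer (fixed eol, no quoting surprises).
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", na = "")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", check.names = FALSE)
}
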