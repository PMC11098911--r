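#' Canonicalize drug names and preferred terms
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal runs
#' of whitespace. All drug-name and PT matching in the package is exact string
#' equality after this canonicalization; no dictionary hierarchy is applied.
#'
#' @param x Character vector.
#' @return Character vector of the same length. Idempotent.
#' @examples
#' canonicalize(c("  Catatonia ", "DTP  vaccine"))
#' @export
canonicalize <- function(x) {
  tolower(trimws(gsub("[[:space:]]+", " ", as.character(x))))
}

# round-half-up at `digits` decimals; base round() is round-half-even.
# The tiny eps guards against values like 57.4999999 that are exact halves
# in decimal but sit just below them in binary.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# FNV-free config fingerprint: md5 of the canonical JSON via a temp file.
config_md5 <- function(x) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             path, useBytes = TRUE)
  unname(tools::md5sum(path))
}

# deterministic TSV writer: fixed column order, "\n" line endings, optional
# "# key=value" header comment lines so reruns are byte-comparable.
write_tsv <- function(df, path, header = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (length(header)) {
    writeLines(paste0("# ", header), con, sep = "\n", useBytes = TRUE)
  }
  cols <- vapply(df, function(col) {
    if (length(col) == 0L) return(character(0))
    if (is.numeric(col) && !is.integer(col)) {
      out <- trimws(formatC(col, format = "fg", digits = 15))
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L, dimnames = list(NULL, names(df)))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df) > 0L) {
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con, useBytes = TRUE)
  }
  invisible(path)
}
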