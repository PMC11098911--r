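#' Read a report set from a JSON Lines file
#'
#' One report object per line, UTF-8, keys in the documented schema order
#' (`report_id`, `age_value`, `age_unit`, `sex`, `country`,
#' `reporter_qualification`, `drugs`, `reactions`, `serious`,
#' `seriousness_criteria`, `outcome`). Drug names and reaction PTs are
#' canonicalized on ingest; input order of reports is preserved. Schema
#' violations and malformed JSON abort with an error naming the offending
#' line; duplicate `report_id` values abort.
#'
#' @param path Path to the JSONL file.
#' @param format Only `"jsonl"` is supported.
#' @return A [report_set()].
#' @seealso [write_report_set()]
#' @export
read_report_set <- function(path, format = "jsonl") {
  format <- match.arg(format, "jsonl")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  reports <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj))
      stop(sprintf("line %d: malformed JSON", i))
    missing <- setdiff(c("report_id", "age_value", "age_unit", "drugs",
                         "reactions"), names(obj))
    if (length(missing))
      stop(sprintf("line %d: missing required field(s): %s", i,
                   paste(missing, collapse = ", ")))
    r <- icsr_report(
      report_id = obj$report_id,
      age_value = obj$age_value,
      age_unit = obj$age_unit,
      sex = obj$sex %||% "unknown",
      country = obj$country %||% "unknown",
      reporter_qualification = obj$reporter_qualification %||% "unknown",
      drugs = obj$drugs,
      reactions = unlist(obj$reactions, use.names = FALSE),
      serious = obj$serious %||% FALSE,
      seriousness_criteria = unlist(obj$seriousness_criteria, use.names = FALSE) %||% character(0),
      outcome = obj$outcome %||% "unknown"
    )
    viol <- validate_report(r)
    if (length(viol))
      stop(sprintf("line %d: invalid report: %s", i,
                   paste(viol, collapse = "; ")))
    reports[[i]] <- r
  }
  report_set(reports, provenance = path)
}

#' Write a report set as JSON Lines
#'
#' One record per line, keys in the fixed schema order, UTF-8, each line
#' newline-terminated. Reactions and seriousness criteria are written sorted
#' and numbers at full precision, so write/read/write is byte-identical.
#'
#' @param rs A [report_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_set <- function(rs, path) {
  stopifnot(inherits(rs, "report_set"))
  n <- length(rs)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (n == 0L) return(invisible(path))
  lines <- vapply(seq_len(n), function(i) {
    drugs <- mapply(function(nm, ro) list(drug_name = nm, role = ro),
                    rs$drug_names[[i]], rs$drug_roles[[i]],
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
    rec <- list(report_id = rs$report_id[i],
                age_value = rs$age_value[i],
                age_unit = rs$age_unit[i],
                sex = rs$sex[i],
                country = rs$country[i],
                reporter_qualification = rs$reporter_qualification[i],
                drugs = drugs,
                reactions = as.list(rs$reactions[[i]]),
                serious = rs$serious[i],
                seriousness_criteria = as.list(rs$seriousness_criteria[[i]]),
                outcome = rs$outcome[i])
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
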