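#' @title Controlled vocabularies of the ICSR schema
#' @description Allowed values for the categorical fields of an individual
#'   case safety report (ICSR). `"unknown"` is an explicit level for sex,
#'   country, reporter qualification and outcome, mirroring the "Unknown"
#'   rows spontaneous-report databases tabulate; age is mandatory because
#'   every analysis in this package is age-stratified.
#' @name icsr_vocab
#' @keywords internal
NULL

AGE_UNITS <- c("days", "months", "years")
SEXES <- c("female", "male", "unknown")
REPORTER_QUALIFICATIONS <- c("physician", "pharmacist",
                             "other_health_professional", "lawyer",
                             "consumer", "unknown")
HCP_QUALIFICATIONS <- c("physician", "pharmacist", "other_health_professional")
DRUG_ROLES <- c("suspect", "interacting", "concomitant")
SERIOUSNESS_CRITERIA <- c("hospitalization", "congenital_anomaly",
                          "disability", "life_threatening", "death",
                          "other_medically_important")
OUTCOMES <- c("recovered", "recovering", "recovered_with_sequelae",
              "not_recovered", "fatal", "unknown")

# fixed key order of the JSON Lines external format
ICSR_KEYS <- c("report_id", "age_value", "age_unit", "sex", "country",
               "reporter_qualification", "drugs", "reactions", "serious",
               "seriousness_criteria", "outcome")

#' Construct a single ICSR report
#'
#' Builds one spontaneous report as a named list, canonicalizing drug names
#' and reaction preferred terms (PTs). Reactions and seriousness criteria are
#' stored sorted so that serialization is canonical; the drug list keeps its
#' reported order.
#'
#' @param report_id Unique report identifier (string).
#' @param age_value Non-negative number.
#' @param age_unit One of `"days"`, `"months"`, `"years"`.
#' @param sex,country,reporter_qualification,outcome Categorical fields; see
#'   the schema vocabularies. `country` is an ISO-3166 alpha-2 code or
#'   `"unknown"`.
#' @param drugs List of drug entries, each a list with `drug_name` and `role`
#'   (`"suspect"`, `"interacting"` or `"concomitant"`).
#' @param reactions Character vector of reaction PTs (at least one).
#' @param serious Logical; must agree with `seriousness_criteria`.
#' @param seriousness_criteria Character vector, subset of the regulatory
#'   seriousness criteria; empty iff `serious` is `FALSE`.
#' @return A list of class `"icsr_report"`.
#' @seealso [validate_report()]
#' @export
icsr_report <- function(report_id, age_value, age_unit, sex = "unknown",
                        country = "unknown",
                        reporter_qualification = "unknown",
                        drugs, reactions, serious = FALSE,
                        seriousness_criteria = character(0),
                        outcome = "unknown") {
  drugs <- lapply(drugs, function(d) {
    list(drug_name = canonicalize(d$drug_name), role = as.character(d$role))
  })
  r <- list(report_id = as.character(report_id),
            age_value = as.numeric(age_value),
            age_unit = as.character(age_unit),
            sex = as.character(sex),
            country = as.character(country),
            reporter_qualification = as.character(reporter_qualification),
            drugs = drugs,
            reactions = sort(unique(canonicalize(reactions))),
            serious = as.logical(serious),
            seriousness_criteria = sort(unique(as.character(seriousness_criteria))),
            outcome = as.character(outcome))
  class(r) <- "icsr_report"
  r
}

#' Validate one ICSR report against the schema invariants
#'
#' Violations are returned, not raised: an empty character vector means the
#' report is valid. Each violation names the offending field and rule.
#'
#' @param r A report as built by [icsr_report()] (a plain named list with the
#'   same fields is accepted).
#' @return Character vector of violation descriptions; `character(0)` if valid.
#' @examples
#' r <- icsr_report("r1", 6, "months",
#'                  drugs = list(list(drug_name = "olanzapine", role = "suspect")),
#'                  reactions = "catatonia")
#' validate_report(r)  # character(0)
#' @export
validate_report <- function(r) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  rid <- r$report_id
  if (is.null(rid) || length(rid) != 1L || is.na(rid) || !nzchar(rid))
    add("report_id: must be a non-empty string")
  if (is.null(r$age_value) || length(r$age_value) != 1L ||
      !is.finite(r$age_value) || r$age_value < 0)
    add("age_value: must be a finite non-negative number")
  if (is.null(r$age_unit) || !identical(length(r$age_unit), 1L) ||
      !(r$age_unit %in% AGE_UNITS))
    add(sprintf("age_unit: must be one of {%s}", paste(AGE_UNITS, collapse = ", ")))
  if (is.null(r$sex) || !(r$sex %in% SEXES))
    add("sex: must be one of {female, male, unknown}")
  if (is.null(r$country) || length(r$country) != 1L ||
      !(identical(r$country, "unknown") || grepl("^[A-Za-z]{2}$", r$country)))
    add("country: must be an ISO-3166 alpha-2 code or \"unknown\"")
  if (is.null(r$reporter_qualification) ||
      !(r$reporter_qualification %in% REPORTER_QUALIFICATIONS))
    add("reporter_qualification: not in the reporter vocabulary")

  if (is.null(r$drugs) || length(r$drugs) < 1L) {
    add("drugs: at least one drug entry is required")
  } else {
    for (d in r$drugs) {
      if (is.null(d$drug_name) || !nzchar(trimws(d$drug_name))) {
        add("drugs: drug_name must be non-empty")
        break
      }
    }
    roles <- vapply(r$drugs, function(d) as.character(d$role %||% NA_character_),
                    character(1))
    if (anyNA(roles) || !all(roles %in% DRUG_ROLES))
      add("drugs: role must be one of {suspect, interacting, concomitant}")
  }

  if (is.null(r$reactions) || length(r$reactions) < 1L ||
      !all(nzchar(r$reactions)))
    add("reactions: at least one non-empty PT is required")

  serious <- isTRUE(r$serious)
  crit <- r$seriousness_criteria
  if (is.null(r$serious) || length(r$serious) != 1L || is.na(r$serious))
    add("serious: must be TRUE or FALSE")
  if (!all(crit %in% SERIOUSNESS_CRITERIA))
    add("seriousness_criteria: unknown criterion")
  if (serious && length(crit) == 0L)
    add("serious: TRUE requires at least one seriousness criterion")
  if (!serious && length(crit) > 0L)
    add("serious: FALSE requires empty seriousness_criteria")
  if (is.null(r$outcome) || !(r$outcome %in% OUTCOMES))
    add("outcome: not in the outcome vocabulary")
  if (identical(r$outcome, "fatal") && !("death" %in% crit))
    add("outcome: fatal requires the death seriousness criterion")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a report set
#'
#' A `report_set` is the package's container for a collection of ICSRs. It is
#' stored column-wise (one vector per scalar field, list columns for drugs,
#' reactions and seriousness criteria) so that querying and scanning stay
#' vectorized on databases of tens of thousands of reports. Age in months is
#' pre-computed at construction.
#'
#' @param reports List of reports as built by [icsr_report()].
#' @param provenance Free-text label recording where the set came from.
#' @return An object of class `"report_set"`.
#' @seealso [read_report_set()], [generate_report_set()]
#' @export
report_set <- function(reports, provenance = "") {
  ids <- vapply(reports, function(r) as.character(r$report_id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate report_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  age_value <- vapply(reports, function(r) as.numeric(r$age_value), numeric(1))
  age_unit <- vapply(reports, function(r) as.character(r$age_unit), character(1))
  new_report_set(
    report_id = ids,
    age_value = age_value,
    age_unit = age_unit,
    sex = vapply(reports, function(r) r$sex, character(1)),
    country = vapply(reports, function(r) r$country, character(1)),
    reporter_qualification = vapply(reports, function(r) r$reporter_qualification,
                                    character(1)),
    drug_names = lapply(reports, function(r)
      vapply(r$drugs, function(d) d$drug_name, character(1))),
    drug_roles = lapply(reports, function(r)
      vapply(r$drugs, function(d) d$role, character(1))),
    reactions = lapply(reports, function(r) r$reactions),
    serious = vapply(reports, function(r) isTRUE(r$serious), logical(1)),
    seriousness_criteria = lapply(reports, function(r)
      as.character(r$seriousness_criteria)),
    outcome = vapply(reports, function(r) r$outcome, character(1)),
    provenance = provenance
  )
}

# low-level columnar constructor; every exported path funnels through here
new_report_set <- function(report_id, age_value, age_unit, sex, country,
                           reporter_qualification, drug_names, drug_roles,
                           reactions, serious, seriousness_criteria, outcome,
                           provenance = "") {
  rs <- list(report_id = report_id,
             age_value = age_value,
             age_unit = age_unit,
             age_months = age_in_months(age_value, age_unit),
             sex = sex,
             country = country,
             reporter_qualification = reporter_qualification,
             drug_names = drug_names,
             drug_roles = drug_roles,
             reactions = reactions,
             serious = serious,
             seriousness_criteria = seriousness_criteria,
             outcome = outcome)
  attr(rs, "provenance") <- provenance
  class(rs) <- "report_set"
  rs
}

#' @export
length.report_set <- function(x) length(x$report_id)

#' Subset a report set
#'
#' @param x A `report_set`.
#' @param i Integer or logical index over reports.
#' @param ... Ignored.
#' @return A `report_set` with the selected reports, provenance preserved.
#' @export
`[.report_set` <- function(x, i, ...) {
  out <- lapply(unclass(x), function(col) col[i])
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- "report_set"
  out
}

#' Extract one report from a report set
#'
#' @param rs A `report_set`.
#' @param i Single index.
#' @return An `icsr_report` list.
#' @export
get_report <- function(rs, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= length(rs))
  drugs <- mapply(function(n, ro) list(drug_name = n, role = ro),
                  rs$drug_names[[i]], rs$drug_roles[[i]],
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  r <- list(report_id = rs$report_id[i],
            age_value = rs$age_value[i],
            age_unit = rs$age_unit[i],
            sex = rs$sex[i],
            country = rs$country[i],
            reporter_qualification = rs$reporter_qualification[i],
            drugs = drugs,
            reactions = rs$reactions[[i]],
            serious = rs$serious[i],
            seriousness_criteria = rs$seriousness_criteria[[i]],
            outcome = rs$outcome[i])
  class(r) <- "icsr_report"
  r
}

#' @export
print.report_set <- function(x, ...) {
  bands <- classify_age_band(x)
  cat(sprintf("<report_set> %d reports", length(x)))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat(sprintf(" [%s]", prov))
  cat("\n")
  tb <- table(factor(bands, levels = c("infant", "child", "adolescent",
                                       "out_of_scope")))
  cat("  age bands: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.report_set <- function(object, ...) {
  bands <- classify_age_band(object)
  out <- list(
    n = length(object),
    provenance = attr(object, "provenance"),
    bands = table(factor(bands, levels = c("infant", "child", "adolescent",
                                           "out_of_scope"))),
    n_serious = sum(object$serious),
    n_drugs = length(unique(unlist(object$drug_names))),
    n_pts = length(unique(unlist(object$reactions)))
  )
  class(out) <- "summary.report_set"
  out
}

#' @export
print.summary.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d distinct drugs, %d distinct PTs\n",
              x$n, x$n_drugs, x$n_pts))
  cat(sprintf("  serious: %d (%.1f%%)\n", x$n_serious, 100 * x$n_serious / x$n))
  print(x$bands)
  invisible(x)
}

#' Define a preferred-term query
#'
#' A PT query is a named, non-empty set of reaction preferred terms; report
#' selection matches reports whose reaction set intersects it. PTs are
#' canonicalized (case-folded, whitespace-trimmed) so matching is exact string
#' equality.
#'
#' @param name Query label.
#' @param pts Character vector of PT strings (at least one).
#' @return An object of class `"pt_query"`.
#' @examples
#' pt_query("catatonia", c("catatonia"))
#' @export
pt_query <- function(name, pts) {
  pts <- sort(unique(canonicalize(pts)))
  pts <- pts[nzchar(pts)]
  if (length(pts) < 1L) stop("pt_query: at least one non-empty PT is required")
  structure(list(name = as.character(name), pts = pts), class = "pt_query")
}

#' @export
print.pt_query <- function(x, ...) {
  cat(sprintf("<pt_query> %s: {%s}\n", x$name, paste(x$pts, collapse = ", ")))
  invisible(x)
}

#' Read a PT-query file
#'
#' The query file is a JSON object mapping query names to arrays of PT
#' strings, e.g. `{"catatonia": ["catatonia"], "posturing": ["posturing"]}`.
#' A default file covering the catatonia family of PTs ships with the package
#' (`system.file("extdata", "pt_queries.json", package = "pvsignal")`).
#'
#' @param path Path to the JSON query file.
#' @return Named list of [pt_query()] objects.
#' @export
read_pt_queries <- function(path) {
  if (!file.exists(path)) stop("PT-query file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || !all(nzchar(names(raw))))
    stop("PT-query file must be a JSON object mapping names to PT arrays")
  out <- lapply(names(raw), function(nm) pt_query(nm, raw[[nm]]))
  names(out) <- names(raw)
  out
}
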