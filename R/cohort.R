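#' Pediatric age bands
#'
#' The analysis stratifies pediatric reports into three half-open age bands
#' measured in months: infants `[0, 24)`, children `[24, 144)` (2-11 years)
#' and adolescents `[144, 216)` (12-17 years). The bands partition
#' `[0, 216)`; ages of 216 months (18 years) and above are out of scope.
#'
#' @format Named list mapping band label to `c(lo, hi)` bounds in months.
#' @export
AGE_BANDS <- list(infant = c(0, 24),
                  child = c(24, 144),
                  adolescent = c(144, 216))

PEDIATRIC_BANDS <- names(AGE_BANDS)

#' Convert an age to months
#'
#' Days are divided by the mean Gregorian month length (30.4375 days);
#' years are multiplied by 12.
#'
#' @param age_value Non-negative numeric vector.
#' @param age_unit Character vector of units (`"days"`, `"months"`,
#'   `"years"`), recycled against `age_value`.
#' @return Numeric vector of ages in months.
#' @examples
#' age_in_months(61, "days")  # 2.004...
#' @export
age_in_months <- function(age_value, age_unit) {
  if (any(!age_unit %in% AGE_UNITS))
    stop("unknown age unit: ",
         paste(unique(age_unit[!age_unit %in% AGE_UNITS]), collapse = ", "))
  factor <- c(days = 1 / 30.4375, months = 1, years = 12)[age_unit]
  unname(age_value * factor)
}

#' Classify reports into pediatric age bands
#'
#' @param r A `report_set`, or a single `icsr_report`.
#' @return Character vector over reports with values `"infant"`, `"child"`,
#'   `"adolescent"` or `"out_of_scope"` (18 years and older).
#' @export
classify_age_band <- function(r) {
  months <- if (inherits(r, "report_set")) r$age_months
            else age_in_months(r$age_value, r$age_unit)
  out <- rep("out_of_scope", length(months))
  out[months < 216] <- "adolescent"
  out[months < 144] <- "child"
  out[months < 24] <- "infant"
  out[is.na(months) | months < 0] <- "out_of_scope"
  out
}

# logical index of reports in a band; band may be a single band label,
# "all-pediatric", or "all" (no age restriction)
band_index <- function(rs, band) {
  if (identical(band, "all")) return(rep(TRUE, length(rs)))
  bands <- classify_age_band(rs)
  if (identical(band, "all-pediatric")) return(bands != "out_of_scope")
  if (!band %in% PEDIATRIC_BANDS)
    stop("unknown band: ", band)
  bands == band
}

# logical index of reports whose reaction set intersects the query
has_pt <- function(rs, q) {
  pts <- q$pts
  vapply(rs$reactions, function(rx) any(rx %in% pts), logical(1))
}

#' Select case reports by PT query and age band
#'
#' Cases are the reports whose reaction set intersects the query PTs and
#' whose age falls in the requested band; input order is preserved.
#'
#' @param rs A `report_set`.
#' @param q A [pt_query()].
#' @param band One of `"infant"`, `"child"`, `"adolescent"`,
#'   `"all-pediatric"` (the default; any age under 18 years) or `"all"`.
#' @return An object of class `"case_set"`: list with `query`, `band` and
#'   `reports` (a `report_set` of the cases).
#' @export
select_cases <- function(rs, q, band = "all-pediatric") {
  stopifnot(inherits(rs, "report_set"), inherits(q, "pt_query"))
  keep <- has_pt(rs, q) & band_index(rs, band)
  structure(list(query = q, band = band, reports = rs[keep]),
            class = "case_set")
}

#' @export
length.case_set <- function(x) length(x$reports)

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf("<case_set> %d cases | query '%s' | band %s\n",
              length(x), x$query$name, x$band))
  invisible(x)
}

#' Rank co-reported preferred terms among cases
#'
#' Counts every PT appearing in the cases' reaction sets other than the query
#' PTs themselves. Percentages are of the number of cases; ranking is by
#' count descending with alphabetical tie-break.
#'
#' @param cs A [select_cases()] result.
#' @param exclude PT query whose terms are excluded from the ranking;
#'   defaults to the case set's own query.
#' @return Data frame with columns `pt`, `n`, `pct`.
#' @export
co_reported_pt_counts <- function(cs, exclude = cs$query) {
  stopifnot(inherits(cs, "case_set"))
  n_cases <- length(cs)
  if (n_cases == 0L)
    stop("co_reported_pt_counts: empty case set (percentages undefined)")
  pts <- unlist(cs$reports$reactions, use.names = FALSE)
  pts <- pts[!pts %in% exclude$pts]
  if (length(pts) == 0L)
    return(data.frame(pt = character(0), n = integer(0), pct = numeric(0)))
  tb <- table(pts)
  ord <- order(-as.integer(tb), names(tb))
  data.frame(pt = names(tb)[ord],
             n = as.integer(tb)[ord],
             pct = percentage(as.integer(tb)[ord], n_cases),
             row.names = NULL)
}

#' Cases featuring two PT queries at once
#'
#' Selects reports whose reactions intersect both queries within a band —
#' e.g. reports coding both catatonia and agitation. The result is always a
#' subset of `select_cases(rs, q1, band)`.
#'
#' @inheritParams select_cases
#' @param q1,q2 Two [pt_query()] objects.
#' @return A `case_set` (its `query` is `q1`; `q2`'s name is recorded in the
#'   `co_query` field).
#' @export
co_occurrence_cases <- function(rs, q1, q2, band = "all-pediatric") {
  keep <- has_pt(rs, q1) & has_pt(rs, q2) & band_index(rs, band)
  out <- structure(list(query = q1, co_query = q2, band = band,
                        reports = rs[keep]),
                   class = "case_set")
  out
}

#' Restrict a case set by reporter qualification
#'
#' The healthcare-professional sensitivity analysis keeps only cases
#' reported by physicians, pharmacists or other health professionals.
#'
#' @param cs A `case_set`.
#' @param qualifications Subset of the reporter vocabulary; defaults to the
#'   three healthcare-professional categories.
#' @return A filtered `case_set`.
#' @export
filter_by_reporter <- function(cs, qualifications = HCP_QUALIFICATIONS) {
  stopifnot(inherits(cs, "case_set"))
  if (!all(qualifications %in% REPORTER_QUALIFICATIONS))
    stop("unknown reporter qualification: ",
         paste(setdiff(qualifications, REPORTER_QUALIFICATIONS), collapse = ", "))
  keep <- cs$reports$reporter_qualification %in% qualifications
  out <- cs
  out$reports <- cs$reports[keep]
  out
}

#' Rank drugs by case count
#'
#' Counts each drug once per report (set semantics) among drug entries whose
#' role is in `roles`. Percentages are of the number of cases; ranking is by
#' count descending with alphabetical tie-break.
#'
#' @param cs A `case_set`.
#' @param roles Drug roles that attribute a report to a drug; default
#'   suspected or interacting, the convention for reported associations
#'   (concomitants are context).
#' @return Data frame with columns `drug_name`, `n`, `pct`.
#' @export
drug_case_counts <- function(cs, roles = c("suspect", "interacting")) {
  stopifnot(inherits(cs, "case_set"))
  n_cases <- length(cs)
  if (n_cases == 0L)
    stop("drug_case_counts: empty case set (percentages undefined)")
  per_report <- mapply(function(nm, ro) unique(nm[ro %in% roles]),
                       cs$reports$drug_names, cs$reports$drug_roles,
                       SIMPLIFY = FALSE)
  drugs <- unlist(per_report, use.names = FALSE)
  if (length(drugs) == 0L)
    return(data.frame(drug_name = character(0), n = integer(0),
                      pct = numeric(0)))
  tb <- table(drugs)
  ord <- order(-as.integer(tb), names(tb))
  data.frame(drug_name = names(tb)[ord],
             n = as.integer(tb)[ord],
             pct = percentage(as.integer(tb)[ord], n_cases),
             row.names = NULL)
}
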