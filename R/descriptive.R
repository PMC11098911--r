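#' Percentage with fixed round-half-up to one decimal
#'
#' Every percentage the package prints uses this rule, so printed counts and
#' percentages always recompute consistently (base `round()` is
#' round-half-even and would not).
#'
#' @param numerator Count(s), `0 <= numerator <= denominator`.
#' @param denominator Positive count(s).
#' @return Numeric vector of percentages at one decimal place.
#' @examples
#' percentage(86, 421)   # 20.4
#' percentage(274, 421)  # 65.1
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("percentage: denominator must be positive")
  if (any(numerator < 0 | numerator > denominator))
    stop("percentage: numerator must be between 0 and denominator")
  round_half_up(100 * numerator / denominator, 1)
}

# one categorical block of the characteristics table: counts and column
# percentages per band plus the pediatric total
tabulate_block <- function(values, bands, levels) {
  cols <- c(PEDIATRIC_BANDS, "total")
  out <- data.frame(category = levels, stringsAsFactors = FALSE)
  for (col in cols) {
    keep <- if (col == "total") rep(TRUE, length(values)) else bands == col
    denom <- sum(keep)
    cnt <- vapply(levels, function(lv) sum(values[keep] == lv), integer(1))
    out[[paste0(col, "_n")]] <- cnt
    out[[paste0(col, "_pct")]] <- if (denom > 0) percentage(cnt, denom)
                                  else rep(NA_real_, length(levels))
  }
  out
}

#' Descriptive characteristics of a case cohort
#'
#' Builds the classic characteristics table of a spontaneous-report cohort:
#' one column per pediatric age band plus the pediatric total, with
#' count (percentage) cells for sex, country and reporter qualification,
#' seriousness and deaths, mean and sample standard deviation of age per
#' band (months for infants, years otherwise), the outcome distribution
#' restricted to reports with a known outcome (its denominator is reported),
#' and the top-drug ranking.
#'
#' @param rs A `report_set`.
#' @param q A [pt_query()] defining the cases.
#' @param roles Drug roles used for the top-drug ranking.
#' @return An object of class `"cohort_summary"`.
#' @export
cohort_characteristics <- function(rs, q, roles = c("suspect", "interacting")) {
  cs <- select_cases(rs, q, band = "all-pediatric")
  n <- length(cs)
  if (n == 0L) stop("cohort_characteristics: empty case set")
  rep_ <- cs$reports
  bands <- classify_age_band(rep_)

  totals <- vapply(PEDIATRIC_BANDS, function(b) sum(bands == b), integer(1))
  totals_df <- data.frame(band = c(PEDIATRIC_BANDS, "total"),
                          n = c(totals, n),
                          pct = percentage(c(totals, n), n))

  countries <- rep_$country
  country_levels <- names(sort(-table(countries)))
  reporter_levels <- c("physician", "pharmacist", "other_health_professional",
                       "lawyer", "consumer", "unknown")
  hcp <- ifelse(rep_$reporter_qualification %in% HCP_QUALIFICATIONS,
                "healthcare_professional", "other_or_unknown")

  age_stats <- lapply(stats::setNames(PEDIATRIC_BANDS, PEDIATRIC_BANDS),
                      function(b) {
    m <- rep_$age_months[bands == b]
    if (length(m) == 0L) return(list(mean = NA_real_, sd = NA_real_,
                                     unit = if (b == "infant") "months" else "years"))
    x <- if (b == "infant") m else m / 12
    list(mean = mean(x), sd = stats::sd(x),
         unit = if (b == "infant") "months" else "years")
  })

  serious_n <- sum(rep_$serious)
  death_n <- sum(rep_$outcome == "fatal")

  out <- list(
    query = q,
    n_cases = n,
    totals = totals_df,
    sex = tabulate_block(rep_$sex, bands, c("female", "male", "unknown")),
    country = tabulate_block(countries, bands, country_levels),
    reporter = tabulate_block(rep_$reporter_qualification, bands,
                              reporter_levels),
    hcp = tabulate_block(hcp, bands,
                         c("healthcare_professional", "other_or_unknown")),
    seriousness = list(n = serious_n, denominator = n,
                       pct = percentage(serious_n, n),
                       deaths = death_n,
                       death_pct = if (serious_n > 0)
                         percentage(death_n, serious_n) else NA_real_),
    age = age_stats,
    outcome = outcome_summary(cs),
    top_drugs = drug_case_counts(cs, roles = roles)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, max_rows = 8, ...) {
  cat(sprintf("Cohort characteristics: '%s' (%d pediatric cases)\n",
              x$query$name, x$n_cases))
  cat("  band totals: ",
      paste(sprintf("%s %d (%.1f)", x$totals$band, x$totals$n, x$totals$pct),
            collapse = ", "), "\n", sep = "")
  for (b in PEDIATRIC_BANDS) {
    a <- x$age[[b]]
    if (!is.na(a$mean))
      cat(sprintf("  age, %s: %.1f (+/-%.1f) %s\n", b, a$mean, a$sd, a$unit))
  }
  cat(sprintf("  serious: %d/%d (%.1f%%), deaths: %d\n",
              x$seriousness$n, x$seriousness$denominator, x$seriousness$pct,
              x$seriousness$deaths))
  oc <- x$outcome
  cat(sprintf("  outcome known: %d/%d (%.1f%%)\n",
              oc$known_n, oc$denominator, oc$known_pct))
  cat("  top drugs:\n")
  td <- utils::head(x$top_drugs, max_rows)
  for (i in seq_len(nrow(td)))
    cat(sprintf("    %s %d (%.1f)\n", td$drug_name[i], td$n[i], td$pct[i]))
  invisible(x)
}

#' Outcome distribution of a case set
#'
#' Percentages use the known-outcome denominator (reports whose outcome is
#' not `"unknown"`), mirroring the "when the outcome was available" pattern
#' of cohort reporting; recovered and recovering are also reported combined.
#'
#' @param cs A `case_set`.
#' @return List with `known_n`, `denominator` (all cases), `known_pct`,
#'   `distribution` (data frame over outcomes with percentages of known) and
#'   `recovered_or_recovering` (n, pct of known).
#' @export
outcome_summary <- function(cs) {
  stopifnot(inherits(cs, "case_set"))
  oc <- cs$reports$outcome
  n <- length(oc)
  known <- oc[oc != "unknown"]
  kn <- length(known)
  levels <- setdiff(OUTCOMES, "unknown")
  if (kn == 0L) {
    dist <- data.frame(outcome = character(0), n = integer(0),
                       pct = numeric(0))
    rr <- list(n = 0L, pct = NA_real_)
  } else {
    cnt <- vapply(levels, function(lv) sum(known == lv), integer(1))
    dist <- data.frame(outcome = levels, n = cnt, pct = percentage(cnt, kn),
                       row.names = NULL)
    nrr <- sum(known %in% c("recovered", "recovering"))
    rr <- list(n = nrr, pct = percentage(nrr, kn))
  }
  list(known_n = kn, denominator = n,
       known_pct = if (n > 0) percentage(kn, n) else NA_real_,
       distribution = dist, recovered_or_recovering = rr)
}

#' Case counts of catatonic feature PTs in a band
#'
#' One row per feature query, in the order given (the order is part of the
#' report layout, not a ranking).
#'
#' @param rs A `report_set`.
#' @param feature_queries List of [pt_query()] objects.
#' @param band Age band label or `"all-pediatric"`.
#' @return Data frame with columns `feature`, `n`.
#' @export
feature_distribution <- function(rs, feature_queries, band = "all-pediatric") {
  if (length(feature_queries) == 0L)
    stop("feature_distribution: feature_queries must be non-empty")
  n <- vapply(feature_queries, function(q) length(select_cases(rs, q, band)),
              integer(1))
  data.frame(feature = vapply(feature_queries, `[[`, character(1), "name"),
             n = n, row.names = NULL)
}
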