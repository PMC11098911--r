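# shared fixture builders; everything is generated in code, no stored data

mk_report <- function(id, age = 15, unit = "years",
                      drugs = list(list(drug_name = "drugx", role = "suspect")),
                      reactions = "catatonia",
                      sex = "unknown", country = "unknown",
                      reporter = "unknown", serious = FALSE,
                      criteria = character(0), outcome = "unknown") {
  icsr_report(report_id = id, age_value = age, age_unit = unit,
              sex = sex, country = country,
              reporter_qualification = reporter, drugs = drugs,
              reactions = reactions, serious = serious,
              seriousness_criteria = criteria, outcome = outcome)
}

# default pediatric world scaled down to n reports (unit tests only; the
# acceptance suite runs the full 50,000-report configuration)
small_cfg <- function(n = 2000L) {
  cfg <- default_pediatric_config(1)
  cfg$n_reports <- as.integer(n)
  cfg
}

null_cfg <- function(cfg = default_pediatric_config(1)) {
  cfg$planted <- lapply(cfg$planted, function(p) { p$rate_ratio <- 1; p })
  cfg
}

q_catatonia <- pt_query("catatonia", "catatonia")

# independent slow-path oracle: per-report loop over get_report()
oracle_case_ids <- function(rs, pts, band) {
  ids <- character(0)
  for (i in seq_len(length(rs))) {
    r <- get_report(rs, i)
    m <- age_in_months(r$age_value, r$age_unit)
    b <- if (m < 24) "infant" else if (m < 144) "child"
         else if (m < 216) "adolescent" else "out_of_scope"
    in_band <- if (band == "all-pediatric") b != "out_of_scope" else b == band
    if (in_band && length(intersect(r$reactions, pts)) > 0)
      ids <- c(ids, r$report_id)
  }
  ids
}
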