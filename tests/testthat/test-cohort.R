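test_that("age normalization converts days and years to months", {
  expect_equal(age_in_months(6, "months"), 6)
  expect_equal(age_in_months(2, "years"), 24)
  expect_equal(age_in_months(61, "days"), 2.004, tolerance = 5e-4)
  expect_error(age_in_months(1, "weeks"), "unknown age unit")
})

test_that("age-band classification follows the half-open month bounds", {
  expect_identical(classify_age_band(mk_report("a", 6, "months")), "infant")
  expect_identical(classify_age_band(mk_report("b", 23, "months")), "infant")
  expect_identical(classify_age_band(mk_report("c", 24, "months")), "child")
  expect_identical(classify_age_band(mk_report("d", 11, "years")), "child")
  expect_identical(classify_age_band(mk_report("e", 12, "years")), "adolescent")
  expect_identical(classify_age_band(mk_report("f", 17, "years")), "adolescent")
  expect_identical(classify_age_band(mk_report("g", 18, "years")), "out_of_scope")
})

test_that("every pediatric report lands in exactly one band", {
  gen <- generate_report_set(small_cfg(4000L), seed = 2)
  bands <- classify_age_band(gen$reports)
  n_ped <- sum(bands != "out_of_scope")
  expect_identical(sum(bands == "infant") + sum(bands == "child") +
                     sum(bands == "adolescent"), n_ped)
  all_ped <- select_cases(gen$reports, q_catatonia, "all-pediatric")
  per_band <- vapply(c("infant", "child", "adolescent"), function(b)
    length(select_cases(gen$reports, q_catatonia, b)), integer(1))
  expect_identical(sum(per_band), length(all_ped))
})

test_that("case selection matches hand counts and an independent scan oracle", {
  rs <- report_set(list(
    mk_report("r1", reactions = c("catatonia", "pyrexia")),
    mk_report("r2", reactions = "pyrexia"),
    mk_report("r3", reactions = "catatonia")
  ))
  cs <- select_cases(rs, q_catatonia)
  expect_length(cs, 2L)
  expect_identical(cs$reports$report_id, c("r1", "r3"))
  expect_length(select_cases(rs, pt_query("posturing", "posturing")), 0L)

  gen <- generate_report_set(small_cfg(3000L), seed = 9)
  for (band in c("infant", "adolescent", "all-pediatric")) {
    got <- select_cases(gen$reports, q_catatonia, band)$reports$report_id
    expect_identical(got, oracle_case_ids(gen$reports, "catatonia", band))
  }
  # band selection is the pediatric selection restricted to the band
  ped <- select_cases(gen$reports, q_catatonia, "all-pediatric")
  bands <- classify_age_band(ped$reports)
  chd <- select_cases(gen$reports, q_catatonia, "child")
  expect_identical(chd$reports$report_id, ped$reports$report_id[bands == "child"])
})

test_that("co-reported PT ranking counts, excludes query terms and breaks ties alphabetically", {
  rs <- report_set(list(
    mk_report("r1", reactions = c("catatonia", "pyrexia")),
    mk_report("r2", reactions = "catatonia"),
    mk_report("r3", reactions = c("catatonia", "pyrexia", "seizure"))
  ))
  out <- co_reported_pt_counts(select_cases(rs, q_catatonia))
  expect_identical(out$pt, c("pyrexia", "seizure"))
  expect_identical(out$n, c(2L, 1L))
  expect_equal(out$pct, c(66.7, 33.3))

  only_q <- report_set(list(mk_report("r1"), mk_report("r2")))
  expect_identical(nrow(co_reported_pt_counts(select_cases(only_q, q_catatonia))), 0L)

  tie <- report_set(list(
    mk_report("r1", reactions = c("catatonia", "seizure")),
    mk_report("r2", reactions = c("catatonia", "agitation"))
  ))
  out <- co_reported_pt_counts(select_cases(tie, q_catatonia))
  expect_identical(out$pt, c("agitation", "seizure"))

  none <- select_cases(rs, pt_query("absent", "absent pt"))
  expect_error(co_reported_pt_counts(none), "empty case set")
})

test_that("co-occurrence selection requires both queries and stays within the primary cases", {
  rs <- report_set(list(
    mk_report("r1", reactions = c("catatonia", "agitation")),
    mk_report("r2", reactions = "catatonia"),
    mk_report("r3", reactions = "agitation")
  ))
  qa <- pt_query("agitation", "agitation")
  both <- co_occurrence_cases(rs, q_catatonia, qa)
  expect_identical(both$reports$report_id, "r1")
  primary <- select_cases(rs, q_catatonia)$reports$report_id
  expect_true(all(both$reports$report_id %in% primary))
})

test_that("reporter filtering keeps HCP cases and is idempotent", {
  rs <- report_set(list(
    mk_report("r1", reporter = "physician"),
    mk_report("r2", reporter = "physician"),
    mk_report("r3", reporter = "consumer"),
    mk_report("r4", reporter = "unknown")
  ))
  cs <- select_cases(rs, q_catatonia)
  hcp <- filter_by_reporter(cs)
  expect_length(hcp, 2L)
  expect_length(filter_by_reporter(cs, character(0)), 0L)
  expect_identical(filter_by_reporter(hcp)$reports$report_id,
                   hcp$reports$report_id)
  expect_error(filter_by_reporter(cs, "nurse"), "unknown reporter")
})

test_that("drug ranking uses set semantics per report and matches a recount", {
  rs <- report_set(list(
    mk_report("r1", drugs = list(list(drug_name = "olanzapine", role = "suspect"),
                                 list(drug_name = "olanzapine", role = "suspect"))),
    mk_report("r2", drugs = list(list(drug_name = "olanzapine", role = "suspect"),
                                 list(drug_name = "lorazepam", role = "concomitant")))
  ))
  out <- drug_case_counts(select_cases(rs, q_catatonia))
  expect_identical(out$drug_name, "olanzapine")   # concomitant excluded
  expect_identical(out$n, 2L)
  expect_equal(out$pct, 100.0)

  gen <- generate_report_set(small_cfg(2500L), seed = 4)
  cs <- select_cases(gen$reports, pt_query("pyrexia", "pyrexia"), "child")
  out <- drug_case_counts(cs)
  # independent recount for three drugs
  for (dn in c("paracetamol", "amoxicillin", "prednisolone")) {
    manual <- 0L
    for (i in seq_len(length(cs$reports))) {
      r <- get_report(cs$reports, i)
      hit <- any(vapply(r$drugs, function(d)
        d$drug_name == dn && d$role %in% c("suspect", "interacting"), logical(1)))
      manual <- manual + as.integer(hit)
    }
    got <- out$n[out$drug_name == dn]
    expect_identical(if (length(got)) got else 0L, manual, label = dn)
  }
  # ranking deterministic: count desc then name asc
  expect_true(all(diff(out$n) <= 0))
  ties <- split(out$drug_name, out$n)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})
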