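test_that("percentages round half-up at one decimal and reject bad inputs", {
  expect_identical(percentage(0, 50), 0)
  expect_identical(percentage(50, 50), 100)
  expect_identical(percentage(1, 8), 12.5)
  expect_identical(percentage(1, 3), 33.3)
  expect_identical(percentage(2, 3), 66.7)
  # half-up, where round-half-even would give 57.4
  expect_identical(percentage(242, 421), 57.5)
  expect_error(percentage(1, 0), "denominator")
  expect_error(percentage(5, 4), "numerator")
})

test_that("cohort characteristics reproduce hand counts per block", {
  rs <- report_set(list(
    mk_report("r1", 14, "years", sex = "female", reporter = "physician"),
    mk_report("r2", 14, "years", sex = "female", reporter = "consumer"),
    mk_report("r3", 5, "years", sex = "male", reporter = "physician"),
    mk_report("r4", 6, "months", sex = "unknown", reporter = "unknown",
              serious = TRUE, criteria = "hospitalization", outcome = "recovered")
  ))
  ch <- cohort_characteristics(rs, q_catatonia)
  expect_identical(ch$n_cases, 4L)
  sex <- ch$sex
  expect_identical(sex$total_n, c(2L, 1L, 1L))
  expect_equal(sex$total_pct, c(50.0, 25.0, 25.0))
  expect_identical(sex[sex$category == "female", "adolescent_n"], 2L)
  expect_identical(ch$seriousness$n, 1L)
  expect_equal(ch$seriousness$pct, 25.0)
  expect_identical(ch$outcome$known_n, 1L)
  # infant age reported in months, others in years
  expect_equal(ch$age$infant$mean, 6)
  expect_identical(ch$age$infant$unit, "months")
  expect_equal(ch$age$adolescent$mean, 14)
  expect_identical(ch$age$adolescent$unit, "years")
})

test_that("column percentages close to 100 within rounding slack", {
  gen <- generate_report_set(small_cfg(6000L), seed = 21)
  ch <- cohort_characteristics(gen$reports, pt_query("pyrexia", "pyrexia"))
  for (block in list(ch$sex, ch$country, ch$reporter)) {
    for (col in c("infant_pct", "child_pct", "adolescent_pct", "total_pct")) {
      s <- sum(block[[col]], na.rm = TRUE)
      if (s > 0) expect_lt(abs(s - 100), 0.3 * max(1, nrow(block) / 3))
    }
    # band columns sum to the total column row by row
    expect_identical(block$infant_n + block$child_n + block$adolescent_n,
                     block$total_n)
  }
})

test_that("cohort cells equal brute-force recounts on synthetic data", {
  gen <- generate_report_set(small_cfg(3000L), seed = 22)
  q <- pt_query("pyrexia", "pyrexia")
  ch <- cohort_characteristics(gen$reports, q)
  cs <- select_cases(gen$reports, q, "all-pediatric")
  bands <- classify_age_band(cs$reports)
  for (sx in c("female", "male")) {
    for (bd in c("infant", "child", "adolescent")) {
      manual <- sum(cs$reports$sex == sx & bands == bd)
      expect_identical(ch$sex[ch$sex$category == sx, paste0(bd, "_n")],
                       manual)
    }
  }
  expect_identical(ch$seriousness$n, sum(cs$reports$serious))
})

test_that("outcome summaries use the known-outcome denominator", {
  rs <- report_set(c(
    lapply(1:4, function(i) mk_report(paste0("k", i), outcome = "recovered")),
    list(mk_report("f1", outcome = "fatal", serious = TRUE,
                   criteria = c("death", "hospitalization"))),
    lapply(1:5, function(i) mk_report(paste0("u", i)))
  ))
  oc <- outcome_summary(select_cases(rs, q_catatonia))
  expect_identical(oc$known_n, 5L)
  expect_identical(oc$denominator, 10L)
  expect_equal(oc$known_pct, 50.0)
  d <- oc$distribution
  expect_equal(d$pct[d$outcome == "recovered"], 80.0)
  expect_equal(d$pct[d$outcome == "fatal"], 20.0)
  expect_identical(oc$recovered_or_recovering$n, 4L)

  all_unknown <- outcome_summary(select_cases(
    report_set(lapply(1:3, function(i) mk_report(paste0("u", i)))), q_catatonia))
  expect_identical(all_unknown$known_n, 0L)
  expect_identical(nrow(all_unknown$distribution), 0L)
})

test_that("feature distributions equal per-feature case counts, zeros on empty bands", {
  gen <- generate_report_set(small_cfg(3000L), seed = 23)
  qs <- lapply(c("posturing", "echolalia", "automatism"),
               function(p) pt_query(p, p))
  fd <- feature_distribution(gen$reports, qs, "child")
  expect_identical(fd$feature, c("posturing", "echolalia", "automatism"))
  for (i in seq_along(qs))
    expect_identical(fd$n[i], length(select_cases(gen$reports, qs[[i]], "child")))
  empty <- report_set(lapply(1:3, function(i) mk_report(paste0("a", i), 30, "years")))
  fd0 <- feature_distribution(empty, qs, "infant")
  expect_identical(fd0$n, c(0L, 0L, 0L))
})

test_that("the pipeline writes parseable tables and the HCP rerun is a subset", {
  gen <- generate_report_set(small_cfg(4000L), seed = 24)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_report_set(gen$reports, f)
  out <- withr::local_tempdir()
  run_pipeline(list(reports = f), out_dir = out)
  expected <- c("cohort_characteristics.tsv", "band_totals.tsv",
                "top_drugs.tsv", "outcome_summary.tsv",
                "outcome_distribution.tsv", "feature_distribution.tsv",
                "co_occurrence.tsv", "manifest.json", "pipeline.log",
                "signals_catatonia_adolescent.tsv",
                "signals_hcp_catatonia_adolescent.tsv")
  for (fn in expected)
    expect_true(file.exists(file.path(out, fn)), label = fn)
  tab <- utils::read.delim(file.path(out, "signals_catatonia_adolescent.tsv"),
                           comment.char = "#")
  expect_identical(names(tab)[1:3], c("drug", "n", "pct_of_cases"))
  hcp <- utils::read.delim(file.path(out, "signals_hcp_catatonia_adolescent.tsv"),
                           comment.char = "#")
  for (i in seq_len(nrow(hcp))) {
    full_n <- tab$n[tab$drug == hcp$drug[i]]
    if (length(full_n)) expect_lte(hcp$n[i], full_n)
  }
  expect_lte(sum(hcp$n), sum(tab$n))
})
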