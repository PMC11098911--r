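test_that("the 2x2 table cells match hand counts and partition the band", {
  mk <- function(id, drug, rx) mk_report(id, 14, "years",
    drugs = list(list(drug_name = drug, role = "suspect")), reactions = rx)
  rs <- report_set(list(
    mk("r1", "drugx", "catatonia"), mk("r2", "drugx", "catatonia"),
    mk("r3", "drugx", "pyrexia"),   mk("r4", "other", "catatonia"),
    mk("r5", "other", "pyrexia"),   mk("r6", "other", "rash")
  ))
  t <- build_contingency(rs, "drugx", q_catatonia, band = "adolescent")
  expect_identical(c(t$a, t$b, t$c, t$d), c(2L, 1L, 1L, 2L))
  expect_identical(t$N, 6L)

  t0 <- build_contingency(rs, "drugx", q_catatonia, band = "infant")
  expect_identical(c(t0$a, t0$b, t0$c, t0$d), c(0L, 0L, 0L, 0L))

  # absent drug is a valid all-but-exposed table, not an error
  t2 <- build_contingency(rs, "ghost", q_catatonia, band = "adolescent")
  expect_identical(c(t2$a, t2$b), c(0L, 0L))
  expect_identical(t2$c + t2$d, 6L)
})

test_that("contingency margins agree with the generator's ground truth", {
  gen <- generate_report_set(small_cfg(2000L), seed = 5)
  for (bd in c("infant", "child", "adolescent")) {
    m <- gen$truth$margins[[bd]]
    for (dn in c("olanzapine", "paracetamol", "dtp vaccine")) {
      t <- build_contingency(gen$reports, dn, q_catatonia, band = bd)
      expect_identical(t$a, as.integer(m$pair[dn, "catatonia"]))
      expect_identical(t$a + t$b, as.integer(m$drug[[dn]]))
      expect_identical(t$a + t$c, as.integer(m$pt[["catatonia"]]))
      expect_identical(t$N, m$n)
    }
  }
})

test_that("ROR point estimate and Woolf CI reproduce hand-evaluated values", {
  bal <- compute_ror(new_contingency(10, 10, 10, 10))
  expect_equal(bal$ror, 1)
  expect_lt(bal$low, 1)
  expect_gt(bal$high, 1)
  expect_equal(log(bal$high) + log(bal$low), 0)  # symmetric on log scale
  expect_false(bal$corrected)

  h <- compute_ror(new_contingency(8, 92, 100, 9800))
  expect_equal(h$ror, 8.522, tolerance = 5e-4)
  expect_equal(h$low, 4.030, tolerance = 5e-4)
  expect_equal(h$high, 18.023, tolerance = 5e-4)

  z <- compute_ror(new_contingency(5, 0, 100, 9900))
  expect_true(z$corrected)
  expect_true(is.finite(z$ror) && is.finite(z$high))

  expect_error(compute_ror(new_contingency(0, 50, 0, 50)), "a = c = 0")
})

test_that("IC shrinkage and the IC025 bound reproduce hand-evaluated values", {
  # O = E makes the shrunk log-ratio exactly zero
  t <- new_contingency(11, 99, 89, 801)
  expect_identical(compute_ic(t)$ic, 0)

  h <- compute_ic(new_contingency(8, 92, 100, 9800))
  expect_equal(h$expected, 1.08)
  expect_equal(h$ic, 2.428, tolerance = 5e-4)
  expect_equal(h$ic025, 1.215, tolerance = 5e-4)

  # closed form vs exact gamma-quantile credibility bound
  ex <- compute_ic(new_contingency(8, 92, 100, 9800), method = "exact")
  expect_lt(abs(h$ic025 - ex$ic025), 0.15)

  none <- compute_ic(new_contingency(0, 100, 50, 9850))
  expect_lt(none$ic, 0)
  expect_lt(none$ic025, none$ic)

  expect_error(compute_ic(new_contingency(0, 0, 0, 0)), "N = 0")
})

test_that("the dual signal criterion requires cases, positive IC025 and ROR lower bound > 1", {
  expect_true(evaluate_signal(6, 2.2, 45.6))
  expect_false(evaluate_signal(4, 3.0, 10))
  expect_false(evaluate_signal(20, -0.1, 1.5))
  expect_false(evaluate_signal(20, 2.0, 1.0))
  expect_identical(evaluate_signal(c(5, 4), c(1, 1), c(2, 2)), c(TRUE, FALSE))
})

test_that("swapping exposure rows inverts the ROR and its interval", {
  set.seed(11)
  for (k in 1:25) {
    cells <- sample(1:40, 4, replace = TRUE)
    r1 <- compute_ror(new_contingency(cells[1], cells[2], cells[3], cells[4]))
    r2 <- compute_ror(new_contingency(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(r2$ror, 1 / r1$ror)
    expect_equal(r2$low, 1 / r1$high)
    expect_equal(r2$high, 1 / r1$low)
  }
})

test_that("shifting a report from drug-no-ADR to drug-with-ADR raises ROR and IC", {
  a <- 5; b <- 50; c <- 20; d <- 500
  for (step in 1:10) {
    r1 <- compute_ror(new_contingency(a, b, c, d))
    r2 <- compute_ror(new_contingency(a + 1, b - 1, c, d))
    i1 <- compute_ic(new_contingency(a, b, c, d))
    i2 <- compute_ic(new_contingency(a + 1, b - 1, c, d))
    expect_gt(r2$ror, r1$ror)
    expect_gt(i2$ic, i1$ic)
    a <- a + 1; b <- b - 1
  }
})

test_that("the scan honours the 5-case threshold and ranks deterministically", {
  mk <- function(id, drug, rx) mk_report(id, 14, "years",
    drugs = list(list(drug_name = drug, role = "suspect")), reactions = rx)
  reports <- c(
    lapply(1:5, function(i) mk(paste0("a", i), "drug5", "catatonia")),
    lapply(1:4, function(i) mk(paste0("b", i), "drug4", "catatonia")),
    lapply(1:60, function(i) mk(paste0("c", i), "filler", "pyrexia"))
  )
  rs <- report_set(reports)
  sc <- run_signal_scan(rs, q_catatonia, band = "adolescent")
  expect_identical(sc$rows$drug, "drug5")
  expect_identical(sc$rows$n, 5L)
  sc4 <- run_signal_scan(rs, q_catatonia, band = "adolescent", min_cases = 4)
  expect_identical(sc4$rows$drug, c("drug5", "drug4"))
})

test_that("the signal verdict is invariant to report order", {
  gen <- generate_report_set(small_cfg(4000L), seed = 12)
  rs <- gen$reports
  sc1 <- run_signal_scan(rs, q_catatonia, band = "adolescent")
  set.seed(99)
  perm <- sample(length(rs))
  sc2 <- run_signal_scan(rs[perm], q_catatonia, band = "adolescent")
  expect_identical(sc1$rows, sc2$rows)
})

test_that("stratum and global backgrounds share cases but not comparators", {
  gen <- generate_report_set(small_cfg(4000L), seed = 13)
  t_s <- build_contingency(gen$reports, "olanzapine", q_catatonia,
                           band = "adolescent", background = "stratum")
  t_g <- build_contingency(gen$reports, "olanzapine", q_catatonia,
                           band = "adolescent", background = "global")
  expect_identical(t_s$a, t_g$a)        # cases are band-restricted in both
  expect_identical(t_g$N, 4000L)        # global pool is the whole database
  expect_lt(t_s$N, t_g$N)
})
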