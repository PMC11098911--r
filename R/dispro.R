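#' Build the 2x2 case/non-case contingency table for one drug
#'
#' Cases are reports in the band whose reactions intersect the PT query;
#' exposure means the report carries the drug with a role in `roles`. With
#' the default stratum background the non-cases come from the same age band;
#' with `background = "global"` cases stay band-restricted but the comparator
#' pool is the whole database.
#'
#' Cells: `a` = drug and query PT, `b` = drug without the PT, `c` = PT
#' without the drug, `d` = neither; `N = a+b+c+d` equals the pool size.
#'
#' @param rs A `report_set`.
#' @param drug Canonical drug name.
#' @param q A [pt_query()].
#' @param band Age band label, `"all-pediatric"` or `"all"`.
#' @param roles Drug roles counting as exposure.
#' @param background `"stratum"` (default) or `"global"`.
#' @return An object of class `"contingency_table"`.
#' @export
build_contingency <- function(rs, drug, q, band = "all-pediatric",
                              roles = c("suspect", "interacting"),
                              background = c("stratum", "global")) {
  background <- match.arg(background)
  drug <- canonicalize(drug)
  in_band <- band_index(rs, band)
  pool <- if (background == "stratum") in_band else rep(TRUE, length(rs))
  case <- has_pt(rs, q) & in_band
  exposed <- mapply(function(nm, ro) any(nm == drug & ro %in% roles),
                    rs$drug_names, rs$drug_roles, USE.NAMES = FALSE)
  a <- sum(pool & case & exposed)
  b <- sum(pool & !case & exposed)
  c <- sum(pool & case & !exposed)
  d <- sum(pool & !case & !exposed)
  new_contingency(a, b, c, d, stratum = band, drug_name = drug,
                  query_name = q$name)
}

new_contingency <- function(a, b, c, d, stratum = "all-pediatric",
                            drug_name = "", query_name = "") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), N = as.integer(a + b + c + d),
                 stratum = stratum, drug_name = drug_name,
                 query_name = query_name),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s [%s]\n",
              x$drug_name, x$query_name, x$stratum))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("ADR", "no ADR")))
  print(m)
  invisible(x)
}

# vectorized ROR with Woolf CI; zero cells get the Haldane-Anscombe +0.5
# on all four cells of that table only
ror_woolf <- function(a, b, c, d, z = 1.96) {
  undef <- (a + c) == 0
  if (any(undef))
    stop("ROR undefined: query PT absent from the background (a = c = 0)")
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  h <- 0.5 * corrected
  aa <- a + h; bb <- b + h; cc <- c + h; dd <- d + h
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  list(ror = ror,
       low = exp(log(ror) - z * se),
       high = exp(log(ror) + z * se),
       corrected = corrected)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; the CI is `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c
#' + 1/d))`. If any cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) and `corrected` is set. An ROR of 1 means the ADR is
#' reported equally often with and without the drug; the association is
#' conventionally called statistically significant when the CI lower bound
#' exceeds 1.
#'
#' @param t A [build_contingency()] table.
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return List with `ror`, `low`, `high`, `corrected`.
#' @examples
#' compute_ror(new_contingency(8, 92, 100, 9800))
#' @export
compute_ror <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_table"))
  ror_woolf(t$a, t$b, t$c, t$d, z = z)
}

# vectorized UMC shrinkage IC; ic025 by the closed-form approximation or the
# exact quantile of the Gamma(O + 0.5, E + 0.5) posterior of the reporting rate
ic_umc <- function(a, b, c, d, method = "approx") {
  N <- a + b + c + d
  if (any(N == 0)) stop("IC undefined on an empty table (N = 0)")
  O <- a
  E <- (a + b) * (a + c) / N
  o5 <- O + 0.5
  ic <- log2(o5 / (E + 0.5))
  ic025 <- if (method == "approx") {
    ic - 3.3 * o5^(-0.5) - 2 * o5^(-1.5)
  } else {
    log2(stats::qgamma(0.025, shape = o5, rate = E + 0.5))
  }
  list(ic = ic, ic025 = ic025, expected = E)
}

#' Information component with its IC025 credibility bound
#'
#' The IC compares the observed count `O = a` of reports carrying both the
#' drug and the ADR with the count expected under independence,
#' `E = (a+b)(a+c)/N`, on a shrunk log2 scale: `IC = log2((O+0.5)/(E+0.5))`.
#' The shrinkage damps spurious disproportionality when `E` is small. A
#' positive IC means more observed than expected reports; screening practice
#' requires the lower 95% credibility bound `IC025` to be positive. The
#' default `IC025` is the closed-form approximation
#' `IC - 3.3 (O+0.5)^(-1/2) - 2 (O+0.5)^(-3/2)`; `method = "exact"` uses the
#' 2.5% quantile of the Gamma(O+0.5, E+0.5) posterior instead.
#'
#' @param t A [build_contingency()] table with `N > 0`.
#' @param method `"approx"` (default) or `"exact"`.
#' @return List with `ic`, `ic025`, `expected`.
#' @examples
#' compute_ic(new_contingency(8, 92, 100, 9800))
#' @export
compute_ic <- function(t, method = c("approx", "exact")) {
  stopifnot(inherits(t, "contingency_table"))
  method <- match.arg(method)
  ic_umc(t$a, t$b, t$c, t$d, method = method)
}

#' Dual disproportionality signal criterion
#'
#' A drug-ADR pair is flagged as a potential safety signal when it has at
#' least `min_cases` case reports, a positive IC025 and an ROR 95% CI lower
#' bound above 1. All three conditions are required.
#'
#' @param n_cases Case count (`a` cell), vectorized.
#' @param ic025 Lower IC credibility bound, vectorized.
#' @param ror_low ROR 95% CI lower bound, vectorized.
#' @param min_cases Minimum case count, default 5.
#' @return Logical vector.
#' @examples
#' evaluate_signal(6, 2.2, 45.6)    # TRUE
#' evaluate_signal(4, 3.0, 10)     # FALSE: below the 5-case threshold
#' evaluate_signal(20, -0.1, 1.5)  # FALSE: IC025 not positive
#' @export
evaluate_signal <- function(n_cases, ic025, ror_low, min_cases = 5) {
  n_cases >= min_cases & ic025 > 0 & ror_low > 1
}

#' Scan every drug for disproportionate reporting of a PT query
#'
#' For each drug accounting for at least `min_cases` cases in the band, the
#' scan builds the 2x2 case/non-case table, computes ROR (Woolf CI) and IC
#' (IC025), and applies the dual signal criterion. Rows are sorted by case
#' count descending, ties alphabetical; non-signal rows are kept with
#' `is_signal = FALSE`. The verdict is invariant to report order.
#'
#' @inheritParams build_contingency
#' @param min_cases Minimum case count for a drug to enter the scan.
#' @param z Normal quantile for the ROR interval.
#' @return An object of class `"dispro_scan"` whose `rows` data frame has
#'   columns `drug`, `n`, `pct_of_cases`, `ror`, `ror_low`, `ror_high`,
#'   `ic`, `ic025`, `corrected`, `is_signal`.
#' @export
run_signal_scan <- function(rs, q, band = "all-pediatric",
                            roles = c("suspect", "interacting"),
                            min_cases = 5, background = c("stratum", "global"),
                            z = 1.96) {
  stopifnot(inherits(rs, "report_set"), inherits(q, "pt_query"))
  background <- match.arg(background)
  in_band <- band_index(rs, band)
  pool <- if (background == "stratum") in_band else rep(TRUE, length(rs))
  case <- logical(length(rs))
  wb <- which(in_band)
  case[wb] <- vapply(rs$reactions[wb], function(rx) any(rx %in% q$pts),
                     logical(1))

  idx <- which(pool)
  # unique (report, drug) pairs with an eligible role, within the pool
  nm <- rs$drug_names[idx]
  ro <- rs$drug_roles[idx]
  lens <- lengths(nm)
  rep_i <- rep.int(idx, lens)
  dn <- unlist(nm, use.names = FALSE)
  dr <- unlist(ro, use.names = FALSE)
  keep <- dr %in% roles
  rep_i <- rep_i[keep]
  dn <- dn[keep]
  all_drugs <- sort(unique(dn))
  dcode <- match(dn, all_drugs)
  dedup <- !duplicated(as.numeric(rep_i) * (max(dcode, 1L) + 1) + dcode)
  pair_i <- rep_i[dedup]
  pair_code <- dcode[dedup]

  n_pool <- length(idx)
  n_case <- sum(case[idx])
  meta <- list(query = q, band = band, roles = roles, min_cases = min_cases,
               background = background, n_pool = n_pool, n_cases = n_case)

  empty <- data.frame(drug = character(0), n = integer(0),
                      pct_of_cases = numeric(0), ror = numeric(0),
                      ror_low = numeric(0), ror_high = numeric(0),
                      ic = numeric(0), ic025 = numeric(0),
                      corrected = logical(0), is_signal = logical(0))
  if (n_case == 0L || length(pair_i) == 0L) {
    return(structure(c(list(rows = empty), meta), class = "dispro_scan"))
  }

  n_drug <- tabulate(pair_code, nbins = length(all_drugs))
  a <- tabulate(pair_code[case[pair_i]], nbins = length(all_drugs))
  keep <- a >= min_cases
  if (!any(keep)) {
    return(structure(c(list(rows = empty), meta), class = "dispro_scan"))
  }
  drugs <- all_drugs[keep]
  a <- a[keep]
  nd <- n_drug[keep]
  b <- nd - a
  c_ <- n_case - a
  d <- n_pool - nd - c_

  ror <- ror_woolf(a, b, c_, d, z = z)
  ic <- ic_umc(a, b, c_, d)
  rows <- data.frame(drug = drugs, n = a,
                     pct_of_cases = percentage(a, n_case),
                     ror = ror$ror, ror_low = ror$low, ror_high = ror$high,
                     ic = ic$ic, ic025 = ic$ic025,
                     corrected = ror$corrected,
                     is_signal = evaluate_signal(a, ic$ic025, ror$low,
                                                 min_cases = min_cases),
                     stringsAsFactors = FALSE)
  rows <- rows[order(-rows$n, rows$drug), , drop = FALSE]
  rownames(rows) <- NULL
  structure(c(list(rows = rows), meta), class = "dispro_scan")
}

#' @export
print.dispro_scan <- function(x, digits = 2, ...) {
  cat(sprintf("Disproportionality scan: '%s' | band %s | background %s\n",
              x$query$name, x$band, x$background))
  cat(sprintf("  %d reports in pool, %d cases; drugs with >= %d cases: %d\n",
              x$n_pool, x$n_cases, x$min_cases, nrow(x$rows)))
  if (nrow(x$rows) == 0L) {
    cat("  (no drug reaches the case threshold)\n")
    return(invisible(x))
  }
  out <- x$rows
  fm <- function(v) formatC(v, format = "f", digits = digits)
  disp <- data.frame(drug = out$drug, n = out$n,
                     `pct` = formatC(out$pct_of_cases, format = "f", digits = 1),
                     ROR = fm(out$ror),
                     `95%CI` = paste0(fm(out$ror_low), "-", fm(out$ror_high)),
                     IC = fm(out$ic), IC025 = fm(out$ic025),
                     signal = ifelse(out$is_signal, "*", ""),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dispro_scan <- function(object, ...) {
  rows <- object$rows
  out <- list(query = object$query$name, band = object$band,
              background = object$background, n_pool = object$n_pool,
              n_cases = object$n_cases, n_scanned = nrow(rows),
              n_signals = sum(rows$is_signal),
              signals = rows[rows$is_signal, , drop = FALSE])
  class(out) <- "summary.dispro_scan"
  out
}

#' @export
print.summary.dispro_scan <- function(x, ...) {
  cat(sprintf("'%s' [%s]: %d cases; %d drugs scanned, %d signal(s)\n",
              x$query, x$band, x$n_cases, x$n_scanned, x$n_signals))
  if (x$n_signals > 0)
    cat("  ", paste(x$signals$drug, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dispro_scan <- function(x, ...) {
  rows <- x$rows
  if (nrow(rows)) {
    rows$query <- x$query$name
    rows$band <- x$band
  } else {
    rows$query <- character(0)
    rows$band <- character(0)
  }
  rows
}
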