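#' Run the full age-stratified analysis pipeline
#'
#' Orchestrates the whole analysis end to end: (optionally) simulate a
#' synthetic database, read the reports, then per pediatric band write the
#' cohort characteristics, top-drug table, outcome summary,
#' disproportionality signal tables for the primary PT query and each
#' feature query, co-occurrence case counts, the feature distribution, and
#' the healthcare-professional sensitivity rerun (the same scan applied to
#' the reporter-filtered set — no separate code path). All outputs are TSV
#' with fixed column order, a header recording the seed and a config
#' fingerprint, and deterministic formatting: identical config and seed
#' reproduce byte-identical files. A JSON manifest and a plain-text log
#' (stage-by-stage input/output counts, including age exclusions) are
#' written alongside.
#'
#' @param config Path to a JSON pipeline config, or an equivalent named
#'   list. Fields: `reports` (path to a JSONL report file) or `simulate`
#'   (list with `scale` and optional `seed`, using
#'   [default_pediatric_config()]); `pt_queries` (path to a PT-query JSON
#'   file; defaults to the file shipped with the package); `primary`
#'   (primary query name, default `"catatonia"`); `features` and
#'   `co_occurrence` (query-name vectors); `bands`; `min_cases`; `roles`;
#'   `background`; `hcp` (reporter qualifications of the sensitivity
#'   rerun); `out_dir`.
#' @param out_dir Overrides the config output directory.
#' @return Invisibly, the output directory. Side effect: TSV tables,
#'   `manifest.json` and `pipeline.log` under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) jsonlite::fromJSON(config,
                                                      simplifyVector = TRUE)
         else config
  defaults <- list(
    primary = "catatonia",
    features = c("malignant catatonia", "withdrawal catatonia", "automatism",
                 "echolalia", "echopraxia", "posturing", "waxy flexibility"),
    co_occurrence = c("agitation", "eating disorder", "speech disorder",
                      "stereotypy", "social avoidant behaviour"),
    bands = c("infant", "child", "adolescent"),
    min_cases = 5L,
    roles = c("suspect", "interacting"),
    background = "stratum",
    hcp = HCP_QUALIFICATIONS,
    out_dir = "pvsignal-out"
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$pt_queries))
    cfg$pt_queries <- system.file("extdata", "pt_queries.json",
                                  package = "pvsignal")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$out_dir, "pipeline.log")
  logcon <- file(logfile, open = "wb")
  on.exit(close(logcon), add = TRUE)
  logline <- function(stage, ...) {
    writeLines(sprintf("[%s] %s", stage, sprintf(...)), logcon,
               useBytes = TRUE)
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  ## stage: acquire reports
  seed <- NA_integer_
  rs <- tryCatch({
    if (!is.null(cfg$simulate)) {
      gcfg <- default_pediatric_config(scale = cfg$simulate$scale %||% 1L)
      seed <- as.integer(cfg$simulate$seed %||% gcfg$seed)
      gen <- generate_report_set(gcfg, seed = seed)
      logline("simulate", "generated %d reports (seed=%d)",
              length(gen$reports), seed)
      if (isTRUE(cfg$simulate$write)) {
        write_report_set(gen$reports, file.path(cfg$out_dir, "reports.jsonl"))
        logline("simulate", "wrote reports.jsonl")
      }
      gen$reports
    } else if (!is.null(cfg$reports)) {
      r <- read_report_set(cfg$reports)
      logline("read", "read %d reports from %s", length(r), cfg$reports)
      r
    } else stop("config needs either 'reports' or 'simulate'")
  }, error = function(e) fail("acquire-reports", e))

  hash_cfg <- cfg
  hash_cfg$out_dir <- NULL
  header <- c(sprintf("seed=%d", seed),
              sprintf("config_md5=%s", config_md5(hash_cfg)))

  queries <- tryCatch(read_pt_queries(cfg$pt_queries),
                      error = function(e) fail("pt-queries", e))
  need <- c(cfg$primary, cfg$features, cfg$co_occurrence)
  missing <- setdiff(need, names(queries))
  if (length(missing))
    fail("pt-queries", simpleError(paste("missing queries:",
                                         paste(missing, collapse = ", "))))
  primary <- queries[[cfg$primary]]

  bands_all <- classify_age_band(rs)
  logline("classify", "bands: infant=%d child=%d adolescent=%d out_of_scope=%d (excluded)",
          sum(bands_all == "infant"), sum(bands_all == "child"),
          sum(bands_all == "adolescent"), sum(bands_all == "out_of_scope"))
  logline("config", "min_cases=%d roles=%s background=%s",
          cfg$min_cases, paste(cfg$roles, collapse = ","), cfg$background)

  scan_to_df <- function(scan) {
    df <- scan$rows
    num3 <- c("ror", "ror_low", "ror_high", "ic", "ic025")
    for (v in num3) df[[v]] <- round(df[[v]], 3)
    df
  }

  ## stage: cohort characteristics
  tryCatch({
    ch <- cohort_characteristics(rs, primary, roles = cfg$roles)
    blocks <- list(sex = ch$sex, country = ch$country, reporter = ch$reporter,
                   hcp = ch$hcp)
    long <- do.call(rbind, lapply(names(blocks), function(nm) {
      b <- blocks[[nm]]
      b$block <- nm
      b[, c("block", setdiff(names(b), "block"))]
    }))
    write_tsv(long, file.path(cfg$out_dir, "cohort_characteristics.tsv"),
              header)
    write_tsv(ch$totals, file.path(cfg$out_dir, "band_totals.tsv"), header)
    write_tsv(ch$top_drugs, file.path(cfg$out_dir, "top_drugs.tsv"), header)
    oc <- ch$outcome
    write_tsv(data.frame(known_n = oc$known_n, denominator = oc$denominator,
                         known_pct = oc$known_pct,
                         recovered_or_recovering_n = oc$recovered_or_recovering$n,
                         recovered_or_recovering_pct = oc$recovered_or_recovering$pct),
              file.path(cfg$out_dir, "outcome_summary.tsv"), header)
    write_tsv(oc$distribution,
              file.path(cfg$out_dir, "outcome_distribution.tsv"), header)
    logline("characteristics", "%d pediatric cases of '%s'", ch$n_cases,
            cfg$primary)
  }, error = function(e) fail("characteristics", e))

  ## stage: signal scans (primary + features), per band, plus HCP rerun
  rs_hcp <- rs[rs$reporter_qualification %in% cfg$hcp]
  logline("hcp-filter", "%d of %d reports from healthcare professionals",
          length(rs_hcp), length(rs))
  for (qname in c(cfg$primary, cfg$features)) {
    q <- queries[[qname]]
    slug <- gsub("[^a-z0-9]+", "_", q$name)
    for (band in cfg$bands) {
      tryCatch({
        scan <- run_signal_scan(rs, q, band = band, roles = cfg$roles,
                                min_cases = cfg$min_cases,
                                background = cfg$background)
        write_tsv(scan_to_df(scan),
                  file.path(cfg$out_dir,
                            sprintf("signals_%s_%s.tsv", slug, band)),
                  header)
        hcp_scan <- run_signal_scan(rs_hcp, q, band = band, roles = cfg$roles,
                                    min_cases = cfg$min_cases,
                                    background = cfg$background)
        write_tsv(scan_to_df(hcp_scan),
                  file.path(cfg$out_dir,
                            sprintf("signals_hcp_%s_%s.tsv", slug, band)),
                  header)
        logline("scan", "%s/%s: %d cases, %d drugs scanned, %d signals (hcp: %d cases)",
                q$name, band, scan$n_cases, nrow(scan$rows),
                sum(scan$rows$is_signal), hcp_scan$n_cases)
      }, error = function(e) fail(sprintf("scan %s/%s", qname, band), e))
    }
  }

  ## stage: feature distribution and co-occurrences per band
  tryCatch({
    fq <- queries[cfg$features]
    fd <- do.call(rbind, lapply(cfg$bands, function(band) {
      d <- feature_distribution(rs, fq, band)
      d$band <- band
      d[, c("band", "feature", "n")]
    }))
    write_tsv(fd, file.path(cfg$out_dir, "feature_distribution.tsv"), header)
    co <- do.call(rbind, lapply(cfg$bands, function(band) {
      do.call(rbind, lapply(cfg$co_occurrence, function(cn) {
        cc <- co_occurrence_cases(rs, primary, queries[[cn]], band)
        data.frame(band = band, co_pt = cn, n = length(cc))
      }))
    }))
    write_tsv(co, file.path(cfg$out_dir, "co_occurrence.tsv"), header)
    logline("features", "feature and co-occurrence tables written")
  }, error = function(e) fail("features", e))

  ## manifest
  manifest <- list(seed = seed, n_reports = length(rs),
                   n_pediatric = sum(bands_all != "out_of_scope"),
                   excluded_out_of_scope = sum(bands_all == "out_of_scope"),
                   config = hash_cfg, config_md5 = config_md5(hash_cfg))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(cfg$out_dir, "manifest.json"), useBytes = TRUE)
  logline("done", "pipeline complete")
  invisible(cfg$out_dir)
}
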