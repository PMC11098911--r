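#' Simulation parameters for a synthetic spontaneous-report database
#'
#' The generator emulates the statistical structure a case/non-case analysis
#' assumes: a large background of reports whose drug exposure depends on age
#' band (vaccines in infants, immunosuppressants and steroids in children,
#' psychotropics in adolescents), per-PT baseline reporting probabilities,
#' and planted drug-PT associations whose reporting-rate ratio is known, so
#' that signal recovery can be tested against ground truth.
#'
#' Reaction model: for each report and each catalog PT, the reporting
#' probability is the PT's baseline `p0` multiplied by `rate_ratio` for every
#' planted association whose drug is present on the report and whose band
#' matches, capped at 1; PTs fire independently. If no PT fires, one PT is
#' drawn proportional to that report's PT probabilities, so every report has
#' at least one reaction (the guaranteed-reaction rule).
#'
#' Drugs: each report carries `1 + Poisson(drugs_per_report_mean)` distinct
#' drugs, drawn without replacement with the band-specific catalog values as
#' weights. Drugs are suspect with probability `suspect_prob`, else
#' concomitant; drugs named in a planted association are always suspect.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; one seed yields one dataset, byte for byte.
#' @param age_band_mix Named probabilities over
#'   `c("infant","child","adolescent","adult")`, summing to 1.
#' @param age_bounds Named list of `c(lo, hi)` month bounds per band. Ages
#'   are sampled uniformly within the band in months, then recorded on the
#'   report in days (under 2 months), months (under 24 months) or whole
#'   years, to exercise unit normalization.
#' @param drug_catalog Named list: drug name -> named numeric vector of
#'   per-band exposure weights.
#' @param drugs_per_report_mean Poisson mean of the extra-drug count.
#' @param pt_catalog Named numeric vector: PT -> baseline reporting
#'   probability.
#' @param planted List of [planted_association()] entries.
#' @param demographics List with `sex_mix`, `country_mix`, `reporter_mix`
#'   (named probability vectors), `p_serious`, `criteria_probs` (per-criterion
#'   probabilities given serious) and `outcome_mix`.
#' @param suspect_prob Probability a generated drug entry is suspect.
#' @return An object of class `"generator_config"`.
#' @seealso [default_pediatric_config()], [generate_report_set()]
#' @export
generator_config <- function(n_reports, seed, age_band_mix, age_bounds,
                             drug_catalog, drugs_per_report_mean = 0.7,
                             pt_catalog, planted = list(),
                             demographics, suspect_prob = 0.8) {
  names(pt_catalog) <- canonicalize(names(pt_catalog))
  pt_catalog <- pt_catalog[order(names(pt_catalog))]
  names(drug_catalog) <- canonicalize(names(drug_catalog))
  planted <- lapply(planted, function(p)
    planted_association(p$drug_name, p$pt, p$age_band, p$rate_ratio))
  cfg <- structure(list(n_reports = as.integer(n_reports),
                        seed = as.integer(seed),
                        age_band_mix = age_band_mix,
                        age_bounds = age_bounds,
                        drug_catalog = drug_catalog,
                        drugs_per_report_mean = drugs_per_report_mean,
                        pt_catalog = pt_catalog,
                        planted = planted,
                        demographics = demographics,
                        suspect_prob = suspect_prob),
                   class = "generator_config")
  cfg
}

#' Plant one drug-PT association in the generator
#'
#' The rate ratio multiplies the PT's baseline reporting probability on
#' reports carrying the drug in the matching band (capped at 1). Because the
#' baseline probabilities are small, the rate ratio coincides, up to
#' vanishing terms, with the reporting odds ratio the scan estimates.
#'
#' @param drug_name,pt Drug and PT; must exist in the catalogs.
#' @param age_band One band label or `"all"`.
#' @param rate_ratio Non-negative finite multiplier.
#' @return A list of class `"planted_association"`.
#' @export
planted_association <- function(drug_name, pt, age_band = "all", rate_ratio) {
  stopifnot(is.finite(rate_ratio), rate_ratio >= 0)
  structure(list(drug_name = canonicalize(drug_name), pt = canonicalize(pt),
                 age_band = age_band, rate_ratio = as.numeric(rate_ratio)),
            class = "planted_association")
}

#' Validate a generator configuration
#'
#' @param cfg A [generator_config()].
#' @return Character vector of problems; `character(0)` if valid.
#' @export
validate_generator_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1)
    add("n_reports: must be >= 1")
  bands <- names(cfg$age_band_mix)
  if (abs(sum(cfg$age_band_mix) - 1) > 1e-9)
    add("age_band_mix: probabilities must sum to 1")
  if (any(cfg$age_band_mix < 0 | cfg$age_band_mix > 1))
    add("age_band_mix: probabilities must be in [0, 1]")
  if (!all(bands %in% names(cfg$age_bounds)))
    add("age_bounds: every band in age_band_mix needs bounds")
  for (dn in names(cfg$drug_catalog)) {
    w <- cfg$drug_catalog[[dn]]
    if (any(w < 0 | w > 1))
      add(sprintf("drug_catalog[%s]: weights must be in [0, 1]", dn))
    if (!all(bands %in% names(w)))
      add(sprintf("drug_catalog[%s]: missing band weight", dn))
  }
  if (any(cfg$pt_catalog < 0 | cfg$pt_catalog > 1))
    add("pt_catalog: probabilities must be in [0, 1]")
  if (!is.numeric(cfg$drugs_per_report_mean) || cfg$drugs_per_report_mean < 0)
    add("drugs_per_report_mean: must be >= 0")
  if (cfg$suspect_prob < 0 || cfg$suspect_prob > 1)
    add("suspect_prob: must be in [0, 1]")
  for (p in cfg$planted) {
    if (!p$drug_name %in% names(cfg$drug_catalog))
      add(sprintf("planted: drug '%s' not in drug_catalog", p$drug_name))
    if (!p$pt %in% names(cfg$pt_catalog))
      add(sprintf("planted: PT '%s' not in pt_catalog", p$pt))
    if (!(p$age_band %in% c(bands, "all")))
      add(sprintf("planted: unknown band '%s'", p$age_band))
  }
  dm <- cfg$demographics
  for (mix in c("sex_mix", "country_mix", "reporter_mix", "outcome_mix")) {
    m <- dm[[mix]]
    if (is.null(m) || abs(sum(m) - 1) > 1e-9 || any(m < 0))
      add(sprintf("demographics$%s: must be probabilities summing to 1", mix))
  }
  if (is.null(dm$p_serious) || dm$p_serious < 0 || dm$p_serious > 1)
    add("demographics$p_serious: must be in [0, 1]")
  v
}

#' Default pediatric spontaneous-report configuration
#'
#' A documented fixture: 50,000 reports per unit of `scale`, with an age mix
#' of 18% infants, 22% children, 25% adolescents and 35% adults; a
#' 25-ingredient catalog giving vaccines high exposure in infants,
#' immunosuppressants and corticosteroids in children, and antipsychotics
#' and other psychotropics in adolescents; a PT catalog containing the
#' catatonia family (catatonia, malignant and withdrawal catatonia,
#' posturing, echolalia, echopraxia, automatism, waxy flexibility) plus
#' common background reaction terms whose baseline probabilities sum to
#' about 1, so that nearly every report fires a reaction naturally; and a
#' set of planted associations echoing the published pediatric landscape
#' (vaccine-catatonia and posturing in infants, haloperidol / ciclosporin /
#' corticosteroid catatonia in children, antipsychotic catatonia in
#' adolescents).
#'
#' @param scale Positive integer; `n_reports = 50000 * scale`.
#' @param seed Default seed recorded in the config.
#' @return A valid [generator_config()].
#' @export
default_pediatric_config <- function(scale = 1, seed = 20221208L) {
  stopifnot(scale >= 1)
  bands <- c("infant", "child", "adolescent", "adult")
  cat_row <- function(i, c, a, ad) {
    stats::setNames(c(i, c, a, ad), bands)
  }
  drug_catalog <- list(
    "pneumococcal vaccine" = cat_row(.30, .05, .02, .005),
    "dtp vaccine"          = cat_row(.28, .06, .03, .005),
    "mmr vaccine"          = cat_row(.22, .05, .01, .002),
    "hepatitis b vaccine"  = cat_row(.18, .03, .01, .01),
    "rotavirus vaccine"    = cat_row(.15, .01, .002, .001),
    "hpv vaccine"          = cat_row(.001, .04, .12, .01),
    "influenza vaccine"    = cat_row(.08, .08, .06, .08),
    "meningococcal vaccine" = cat_row(.04, .05, .06, .005),
    "ciclosporin"          = cat_row(.005, .06, .02, .02),
    "prednisolone"         = cat_row(.01, .08, .04, .05),
    "methylprednisolone"   = cat_row(.005, .05, .03, .03),
    "methotrexate"         = cat_row(.001, .03, .02, .03),
    "olanzapine"           = cat_row(.0005, .01, .10, .06),
    "risperidone"          = cat_row(.001, .03, .09, .04),
    "quetiapine"           = cat_row(.0005, .008, .06, .05),
    "aripiprazole"         = cat_row(.0005, .008, .05, .03),
    "haloperidol"          = cat_row(.001, .012, .03, .03),
    "chlorpromazine"       = cat_row(.0002, .002, .02, .02),
    "lorazepam"            = cat_row(.002, .01, .04, .05),
    "valproic acid"        = cat_row(.002, .02, .05, .04),
    "fluoxetine"           = cat_row(.0002, .008, .06, .05),
    "methylphenidate"      = cat_row(.0005, .06, .05, .01),
    "ondansetron"          = cat_row(.01, .04, .03, .04),
    "paracetamol"          = cat_row(.10, .12, .10, .12),
    "amoxicillin"          = cat_row(.12, .10, .05, .06)
  )
  pt_catalog <- c(
    # common background terms: keep the per-report PT probability mass near 1
    # so the guaranteed-reaction rule rarely fires
    "pyrexia" = .10, "nausea" = .10, "vomiting" = .09, "rash" = .09,
    "headache" = .08, "drug ineffective" = .08, "somnolence" = .07,
    "diarrhoea" = .07, "dizziness" = .06, "fatigue" = .06, "urticaria" = .05,
    "insomnia" = .04, "agitation" = .04, "seizure" = .03,
    # catatonia family and feature terms
    "catatonia" = .002, "malignant catatonia" = .0004,
    "withdrawal catatonia" = .0002, "posturing" = .003, "echolalia" = .0015,
    "echopraxia" = .0005, "automatism" = .001, "waxy flexibility" = .0005,
    "unresponsive to stimuli" = .004, "neuroleptic malignant syndrome" = .002,
    "speech disorder" = .004, "stereotypy" = .001, "eating disorder" = .001,
    "social avoidant behaviour" = .0005
  )
  planted <- list(
    planted_association("dtp vaccine", "catatonia", "infant", 8),
    planted_association("pneumococcal vaccine", "posturing", "infant", 6),
    planted_association("mmr vaccine", "echolalia", "infant", 7),
    planted_association("haloperidol", "catatonia", "child", 30),
    planted_association("ciclosporin", "catatonia", "child", 12),
    planted_association("prednisolone", "catatonia", "child", 10),
    planted_association("hpv vaccine", "posturing", "child", 16),
    planted_association("olanzapine", "catatonia", "adolescent", 25),
    planted_association("risperidone", "catatonia", "adolescent", 15),
    planted_association("chlorpromazine", "posturing", "adolescent", 40),
    planted_association("olanzapine", "withdrawal catatonia", "adolescent", 30)
  )
  demographics <- list(
    sex_mix = c(female = .47, male = .50, unknown = .03),
    country_mix = c(US = .60, CA = .04, DE = .03, GB = .03, FR = .02,
                    IT = .02, CN = .015, AU = .015, JP = .02, BR = .02,
                    IN = .02, ES = .015, NL = .01, SE = .01, unknown = .135),
    reporter_mix = c(physician = .32, other_health_professional = .15,
                     pharmacist = .03, consumer = .18, lawyer = .005,
                     unknown = .315),
    p_serious = .45,
    criteria_probs = c(hospitalization = .70, life_threatening = .10,
                       disability = .04, congenital_anomaly = .01,
                       other_medically_important = .30),
    outcome_mix = c(unknown = .62, recovered = .22, recovering = .08,
                    not_recovered = .05, recovered_with_sequelae = .015,
                    fatal = .015)
  )
  generator_config(
    n_reports = 50000L * as.integer(scale),
    seed = seed,
    age_band_mix = c(infant = .18, child = .22, adolescent = .25, adult = .35),
    age_bounds = list(infant = c(0, 24), child = c(24, 144),
                      adolescent = c(144, 216), adult = c(216, 1188)),
    drug_catalog = drug_catalog,
    drugs_per_report_mean = 0.7,
    pt_catalog = pt_catalog,
    planted = planted,
    demographics = demographics,
    suspect_prob = 0.8
  )
}

#' Generate a synthetic report set with ground truth
#'
#' Produces exactly `cfg$n_reports` reports, each with at least one drug and
#' one reaction. Identical configuration (including seed) reproduces the
#' identical set byte for byte: the generator pins the RNG kind and draws in
#' a fixed documented order (band, age, drug count, drugs per report in
#' index order, roles, the reaction matrix column-major, guaranteed-reaction
#' draws in index order, then demographics field by field).
#'
#' @param cfg A valid [generator_config()].
#' @param seed Overrides `cfg$seed` when given.
#' @return List with `reports` (a [report_set()]) and `truth` (class
#'   `"ground_truth"`: the planted associations plus realized per-band
#'   margins — reports per drug, per PT and per drug-PT pair, counting
#'   suspect/interacting roles).
#' @export
generate_report_set <- function(cfg, seed = cfg$seed) {
  problems <- validate_generator_config(cfg)
  if (length(problems))
    stop("invalid generator_config:\n  ", paste(problems, collapse = "\n  "))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- cfg$n_reports
  bands <- names(cfg$age_band_mix)
  drugs <- names(cfg$drug_catalog)
  n_drug <- length(drugs)
  pts <- names(cfg$pt_catalog)  # sorted by generator_config()
  n_pt <- length(pts)
  w <- vapply(cfg$drug_catalog, function(x) x[bands], numeric(length(bands)))
  # w: bands x drugs matrix of sampling weights

  ## 1. band and age (latent months, uniform within band)
  band <- sample(bands, n, replace = TRUE, prob = cfg$age_band_mix)
  lo <- vapply(cfg$age_bounds, `[`, numeric(1), 1L)[band]
  hi <- vapply(cfg$age_bounds, `[`, numeric(1), 2L)[band]
  months <- unname(lo + stats::runif(n) * (hi - lo))

  ## 2. drugs per report: 1 + Poisson, capped at the catalog size
  k <- pmin(1L + stats::rpois(n, cfg$drugs_per_report_mean), n_drug)
  drug_idx <- vector("list", n)
  for (bd in bands) {
    wb <- w[bd, ]
    sel <- which(band == bd)
    one <- sel[k[sel] == 1L]
    if (length(one))
      drug_idx[one] <- as.list(sample.int(n_drug, length(one), replace = TRUE,
                                          prob = wb))
    multi <- sel[k[sel] > 1L]
    for (i in multi)
      drug_idx[[i]] <- sort(sample.int(n_drug, k[i], prob = wb))
  }

  ## 3. roles: suspect w.p. suspect_prob, else concomitant;
  ##    planted-association drugs always suspect
  planted_drugs <- unique(vapply(cfg$planted, `[[`, character(1), "drug_name"))
  total <- sum(lengths(drug_idx))
  u_role <- stats::runif(total)
  role_flat <- ifelse(u_role < cfg$suspect_prob, "suspect", "concomitant")
  flat_drug <- unlist(drug_idx, use.names = FALSE)
  role_flat[drugs[flat_drug] %in% planted_drugs] <- "suspect"
  role_split <- split(role_flat, factor(rep.int(seq_len(n), lengths(drug_idx)),
                                        levels = seq_len(n)))
  names(role_split) <- NULL

  ## 4. reactions: baseline probabilities boosted by matching planted pairs
  P <- matrix(cfg$pt_catalog, nrow = n, ncol = n_pt, byrow = TRUE)
  M <- matrix(FALSE, nrow = n, ncol = n_drug)
  M[cbind(rep.int(seq_len(n), lengths(drug_idx)), flat_drug)] <- TRUE
  for (p in cfg$planted) {
    j <- match(p$pt, pts)
    dj <- match(p$drug_name, drugs)
    hit <- M[, dj] & (p$age_band == "all" | band == p$age_band)
    P[hit, j] <- pmin(1, P[hit, j] * p$rate_ratio)
  }
  R <- matrix(stats::runif(n * n_pt), nrow = n, ncol = n_pt) < P
  none <- which(rowSums(R) == 0L)
  for (i in none) {
    R[i, sample.int(n_pt, 1L, prob = P[i, ])] <- TRUE
  }
  hits <- which(R)
  row_i <- ((hits - 1L) %% n) + 1L
  col_j <- ((hits - 1L) %/% n) + 1L
  ord <- order(row_i, col_j)
  reactions <- split(pts[col_j[ord]], factor(row_i[ord], levels = seq_len(n)))
  names(reactions) <- NULL

  ## 5. demographics
  dm <- cfg$demographics
  sex <- sample(names(dm$sex_mix), n, replace = TRUE, prob = dm$sex_mix)
  country <- sample(names(dm$country_mix), n, replace = TRUE,
                    prob = dm$country_mix)
  reporter <- sample(names(dm$reporter_mix), n, replace = TRUE,
                     prob = dm$reporter_mix)
  serious <- stats::runif(n) < dm$p_serious
  crit_draw <- matrix(stats::runif(n * length(dm$criteria_probs)), nrow = n) <
    matrix(dm$criteria_probs, nrow = n, ncol = length(dm$criteria_probs),
           byrow = TRUE)
  outcome <- sample(names(dm$outcome_mix), n, replace = TRUE,
                    prob = dm$outcome_mix)
  serious <- serious | outcome == "fatal"
  crit_names <- names(dm$criteria_probs)
  criteria <- lapply(seq_len(n), function(i) {
    if (!serious[i]) return(character(0))
    cr <- crit_names[crit_draw[i, ]]
    if (outcome[i] == "fatal") cr <- c(cr, "death")
    if (length(cr) == 0L) cr <- "other_medically_important"
    sort(unique(cr))
  })

  ## 6. recorded age value and unit (days < 2 months, months < 24, else years)
  age_unit <- ifelse(months < 2, "days",
                     ifelse(months < 24, "months", "years"))
  age_value <- ifelse(age_unit == "days", round(months * 30.4375),
                      ifelse(age_unit == "months", floor(months),
                             floor(months / 12)))

  rs <- new_report_set(
    report_id = sprintf("SYN-%07d", seq_len(n)),
    age_value = age_value,
    age_unit = age_unit,
    sex = sex,
    country = country,
    reporter_qualification = reporter,
    drug_names = lapply(drug_idx, function(ix) drugs[ix]),
    drug_roles = role_split,
    reactions = reactions,
    serious = serious,
    seriousness_criteria = criteria,
    outcome = outcome,
    provenance = sprintf("synthetic seed=%d n=%d", seed, n)
  )

  ## realized margins from the generation matrices (suspect/interacting
  ## exposure, i.e. excluding concomitant-only entries)
  role_eligible <- role_flat %in% c("suspect", "interacting")
  Me <- matrix(FALSE, nrow = n, ncol = n_drug)
  Me[cbind(rep.int(seq_len(n), lengths(drug_idx))[role_eligible],
           flat_drug[role_eligible])] <- TRUE
  margins <- lapply(stats::setNames(bands, bands), function(bd) {
    sel <- band == bd
    drug_n <- colSums(Me[sel, , drop = FALSE])
    pt_n <- colSums(R[sel, , drop = FALSE])
    pair <- crossprod(Me[sel, , drop = FALSE], R[sel, , drop = FALSE])
    dimnames(pair) <- list(drugs, pts)
    list(n = sum(sel),
         drug = stats::setNames(as.integer(drug_n), drugs),
         pt = stats::setNames(as.integer(pt_n), pts),
         pair = pair)
  })
  truth <- structure(list(planted = cfg$planted, margins = margins),
                     class = "ground_truth")
  list(reports = rs, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d planted association(s), margins over %d band(s)\n",
              length(x$planted), length(x$margins)))
  for (p in x$planted)
    cat(sprintf("  %s x %s [%s] rate ratio %.1f\n",
                p$drug_name, p$pt, p$age_band, p$rate_ratio))
  invisible(x)
}
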