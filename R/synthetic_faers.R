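#' Default preferred-term catalogue for the report simulator
#'
#' Cardiac-disorders PTs carry the event vocabulary of the study (with
#' per-report background reporting probabilities in the full database);
#' the non-cardiac PTs provide the co-reported background across other
#' system organ classes.
#'
#' @return A tibble with columns `pt`, `soc`, `base_prob`.
#' @export
default_pt_catalog <- function() {
  tibble::tribble(
    ~pt,                             ~soc,                 ~base_prob,
    "cardiotoxicity",                "cardiac disorders",  0.0006,
    "cardiac dysfunction",           "cardiac disorders",  0.0006,
    "cardiac failure",               "cardiac disorders",  0.0050,
    "cardiac failure congestive",    "cardiac disorders",  0.0030,
    "tachycardia",                   "cardiac disorders",  0.0070,
    "cardiac disorder",              "cardiac disorders",  0.0060,
    "atrial fibrillation",           "cardiac disorders",  0.0060,
    "left ventricular dysfunction",  "cardiac disorders",  0.0010,
    "pericardial effusion",          "cardiac disorders",  0.0050,
    "cardiomyopathy",                "cardiac disorders",  0.0015,
    "mitral valve incompetence",     "cardiac disorders",  0.0006,
    "angina pectoris",               "cardiac disorders",  0.0030,
    "ventricular hypokinesia",       "cardiac disorders",  0.0003,
    "nausea",        "gastrointestinal disorders",                    0.060,
    "diarrhoea",     "gastrointestinal disorders",                    0.050,
    "vomiting",      "gastrointestinal disorders",                    0.030,
    "fatigue",       "general disorders and administration site conditions", 0.060,
    "pyrexia",       "general disorders and administration site conditions", 0.020,
    "drug ineffective", "general disorders and administration site conditions", 0.050,
    "ejection fraction decreased", "investigations",                  0.004,
    "neutropenia",   "blood and lymphatic system disorders",          0.020,
    "anaemia",       "blood and lymphatic system disorders",          0.020,
    "alopecia",      "skin and subcutaneous tissue disorders",        0.010,
    "rash",          "skin and subcutaneous tissue disorders",        0.020,
    "headache",      "nervous system disorders",                      0.030,
    "dyspnoea",      "respiratory, thoracic and mediastinal disorders", 0.025
  )
}

#' Default injected drug-event signals
#'
#' Reporting-odds-ratio targets for the cardiac PTs of the antibody-drug
#' conjugate class; drug `"*"` applies the signal to every target drug.
#'
#' @return A tibble with columns `drug`, `pt`, `ror`.
#' @export
default_injected_signals <- function() {
  tibble::tribble(
    ~drug, ~pt,                            ~ror,
    "*",   "cardiotoxicity",               30.99,
    "*",   "cardiac dysfunction",          18.00,
    "*",   "ventricular hypokinesia",      11.55,
    "*",   "left ventricular dysfunction",  8.00,
    "*",   "mitral valve incompetence",     7.82,
    "*",   "cardiomyopathy",                3.72,
    "*",   "cardiac failure",               3.18,
    "*",   "cardiac failure congestive",    1.80,
    "*",   "angina pectoris",               1.77,
    "*",   "atrial fibrillation",           1.60,
    "*",   "tachycardia",                   1.47,
    "*",   "cardiac disorder",              1.39,
    "*",   "pericardial effusion",          1.39
  )
}

#' Default cancer indication mix with cardiac risk gradient
#'
#' Breast cancer dominates the indication mix, as it does for marketed
#' antibody-drug conjugates; `cardiac_odds_multiplier` scales the odds of
#' every cardiac PT for reports with that indication (bile duct highest,
#' bladder lowest).
#'
#' @return A tibble with columns `cancer`, `prob`,
#'   `cardiac_odds_multiplier`.
#' @export
default_indication_mix <- function() {
  tibble::tribble(
    ~cancer,            ~prob, ~cardiac_odds_multiplier,
    "breast cancer",    0.5427, 1.00,
    "gastric cancer",   0.07,   0.60,
    "lung cancer",      0.06,   0.75,
    "bladder cancer",   0.05,   0.50,
    "bile duct cancer", 0.03,   2.00,
    "ovarian cancer",   0.06,   0.90,
    "lymphoma",         0.07,   0.85,
    "cervical cancer",  0.04,   0.80,
    "prostate cancer",  0.03,   1.40,
    "brain cancer",     0.02,   1.50,
    "anal cancer",      0.02,   1.60,
    "adrenal cancer",   0.0073, 1.30
  )
}

#' Configuration for the synthetic report database
#'
#' Every knob of the generative model behind the synthetic FAERS-like
#' database. The defaults encode the study conditions this package
#' emulates: a 2019-2023 reporting window, nine target antibody-drug
#' conjugates, cardiac PT signals at the reported ROR magnitudes, a
#' female-dominated breast-cancer-heavy population, right-skewed
#' log-normal onset times, dexamethasone as a protective concomitant
#' partner, 20% duplicated case versions and realistic per-field
#' missingness.
#'
#' Injected signals are parameterised directly as reporting odds ratios:
#' for each (drug, PT) pair the log-odds of that PT is shifted by
#' `log(ror)` for reports exposed to the drug, so the marginal 2x2 ROR of
#' a rare PT recovers the configured value. Cardiac covariate effects
#' (age, male sex, fatality, cancer type) act on the conditional log-odds
#' of every cardiac PT.
#'
#' @param n_reports Number of unique reports (before duplicate versions).
#' @param seed Integer seed; the whole database is reproducible from it.
#' @param target_drugs Target drug names.
#' @param exposure_fraction Fraction of reports with a target drug as
#'   primary suspect.
#' @param background_pt_catalog Tibble `pt`, `soc`, `base_prob`.
#' @param injected_signals Tibble `drug` (or `"*"`), `pt`, `ror`.
#' @param demographic_model Sex mix, age/weight distributions and
#'   per-field missingness rates.
#' @param cardiac_effects Log-odds effects on cardiac PTs: `age_log_or`
#'   (per year, centred at `age_ref`), `male_log_or`, `fatal_log_or`.
#' @param outcome_model Outcome codes and probabilities (one primary
#'   outcome per report).
#' @param onset_model Log-normal onset-day model: per-sex medians,
#'   `sdlog`, and a multiplier for reports older than 65.
#' @param combo_model Concomitant partner drug, its co-exposure fraction
#'   among exposed reports, and per-PT odds multipliers applying to
#'   reports exposed to both.
#' @param indication_mix Tibble `cancer`, `prob`,
#'   `cardiac_odds_multiplier`.
#' @param co_report_rate Fraction of cardiac reports carrying at least one
#'   non-cardiac co-reported PT (calibrated after the PT draws; `NULL`
#'   disables the calibration).
#' @param duplicate_rate Fraction of cases emitted as an extra, earlier
#'   case version.
#' @param crossdup_rate Fraction of cases cloned under a fresh caseid with
#'   identical screened fields (removed by the cross-field screen).
#' @param bad_date_rate Fraction of dated reports corrupted with an
#'   event-before-start swap or a partial start date.
#' @param report_window First and last submission date.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 50000,
                       seed = 1L,
                       target_drugs = c("enhertu", "polivy", "padcev",
                                        "trodelvy", "tivdak", "akalux",
                                        "zynlonta", "rc48", "elahere"),
                       exposure_fraction = 0.1,
                       background_pt_catalog = default_pt_catalog(),
                       injected_signals = default_injected_signals(),
                       demographic_model = list(
                         female_fraction = 0.8,
                         unk_sex_fraction = 0.002,
                         age_mean = 60, age_sd = 13.5,
                         weight_meanlog = log(70), weight_sdlog = 0.25,
                         missing = list(age = 0.46, weight = 0.72,
                                        sex = 0.02, country = 0.05,
                                        event_dt = 0.45, start_dt = 0.30,
                                        outcome = 0.10)
                       ),
                       cardiac_effects = list(age_log_or = 0.013,
                                              age_ref = 60,
                                              male_log_or = log(0.42),
                                              fatal_log_or = log(0.75)),
                       outcome_model = list(
                         codes = c("DE", "LT", "HO", "DS", "CA", "RI", "OT"),
                         probs = c(0.115, 0.03, 0.25, 0.012, 0.001, 0.002,
                                   0.59)
                       ),
                       onset_model = list(median_days_female = 85,
                                          median_days_male = 28,
                                          sdlog = 1.0,
                                          age65_multiplier = 1.2),
                       combo_model = list(
                         partner = "dexamethasone",
                         co_exposure_fraction = 0.2,
                         background_fraction = 0.05,
                         multipliers = c("cardiac failure" = 0.27,
                                         "pericardial effusion" = 0.34,
                                         "cardiomyopathy" = 0.35)
                       ),
                       indication_mix = default_indication_mix(),
                       co_report_rate = 0.65,
                       duplicate_rate = 0.2,
                       crossdup_rate = 0.01,
                       bad_date_rate = 0.05,
                       report_window = c("2019-01-01", "2023-09-30")) {
  cfg <- list(
    n_reports = as.integer(n_reports), seed = as.integer(seed),
    target_drugs = target_drugs, exposure_fraction = exposure_fraction,
    background_pt_catalog = tibble::as_tibble(background_pt_catalog),
    injected_signals = tibble::as_tibble(injected_signals),
    demographic_model = demographic_model,
    cardiac_effects = cardiac_effects, outcome_model = outcome_model,
    onset_model = onset_model, combo_model = combo_model,
    indication_mix = tibble::as_tibble(indication_mix),
    co_report_rate = co_report_rate, duplicate_rate = duplicate_rate,
    crossdup_rate = crossdup_rate, bad_date_rate = bad_date_rate,
    report_window = as.Date(report_window)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_reports <= 0) stop("n_reports must be positive")
  cat <- cfg$background_pt_catalog
  if (any(cat$base_prob <= 0 | cat$base_prob >= 1)) {
    stop("base reporting probabilities must lie in (0, 1)")
  }
  if (anyDuplicated(cat$pt)) stop("duplicate PTs in the catalogue")
  sig <- cfg$injected_signals
  if (nrow(sig)) {
    if (any(sig$ror <= 0)) stop("injected true RORs must be positive")
    if (!all(sig$pt %in% cat$pt)) {
      stop("injected signal references PT(s) absent from the catalogue: ",
           paste(setdiff(sig$pt, cat$pt), collapse = ", "))
    }
    bad_drug <- !(sig$drug %in% c("*", cfg$target_drugs))
    if (any(bad_drug)) {
      stop("injected signal references unknown drug(s): ",
           paste(unique(sig$drug[bad_drug]), collapse = ", "))
    }
  }
  rates <- c(cfg$exposure_fraction, cfg$duplicate_rate, cfg$crossdup_rate,
             cfg$bad_date_rate, unlist(cfg$demographic_model$missing),
             cfg$co_report_rate %||% 0)
  if (any(rates < 0 | rates > 1)) stop("rates/probabilities must be in [0, 1]")
  if (abs(sum(cfg$indication_mix$prob) - 1) > 1e-6) {
    stop("indication mix probabilities must sum to 1")
  }
  if (abs(sum(cfg$outcome_model$probs) - 1) > 1e-6) {
    stop("outcome probabilities must sum to 1")
  }
  combo_pts <- names(cfg$combo_model$multipliers)
  if (length(combo_pts) && !all(combo_pts %in% cat$pt)) {
    stop("combo multipliers reference PT(s) absent from the catalogue")
  }
  invisible(cfg)
}

#' Term map matching a simulation configuration
#'
#' The PT to SOC mapping implied by the catalogue of a [sim_config()],
#' usable wherever a MedDRA-like term map is required.
#'
#' @param config A `sim_config`.
#' @return A tibble with columns `pt` and `soc`.
#' @export
sim_term_map <- function(config) {
  config$background_pt_catalog[, c("pt", "soc")]
}

# sample() treats a length-1 x as 1:x; this does not
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

.background_drug_pool <- c("paclitaxel", "carboplatin", "pembrolizumab",
                           "letrozole", "tamoxifen", "capecitabine",
                           "aspirin", "metformin", "atezolizumab",
                           "cyclophosphamide", "doxorubicin", "rituximab")

#' Simulate a FAERS-like report database with known ground truth
#'
#' Draws a complete synthetic spontaneous-report database under the
#' generative model of [sim_config()]: exposure, demographics, outcome,
#' indication, per-PT reaction draws on the logistic reporting-odds scale,
#' log-normal onset dates, concomitant-partner risk modification,
#' duplicate case versions, near-duplicate caseid clones, partial/invalid
#' dates and per-field missingness. The same seed and configuration always
#' give byte-identical tables.
#'
#' @param config A `sim_config`.
#' @return A list with `tables` (named list of tibbles in the FAERS
#'   dialect: demo, drug, reac, outc, ther, indi), `truth` (injected
#'   parameters, per-report latent state, per-PT exposure counts and the
#'   expected unique-case count) and `config`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_reports
  dm <- config$demographic_model
  cat <- config$background_pt_catalog
  p_pt <- nrow(cat)
  is_cardiac_col <- normalize_term(cat$soc) == "cardiac disorders"

  # --- latent per-report state -------------------------------------------
  exposed <- stats::runif(n) < config$exposure_fraction
  adc <- rep(NA_character_, n)
  adc[exposed] <- sample(config$target_drugs, sum(exposed), replace = TRUE)

  sex <- sample(c("F", "M", "UNK"), n, replace = TRUE,
                prob = c(dm$female_fraction * (1 - dm$unk_sex_fraction),
                         (1 - dm$female_fraction) * (1 - dm$unk_sex_fraction),
                         dm$unk_sex_fraction))
  age <- round(pmin(95, pmax(18, stats::rnorm(n, dm$age_mean, dm$age_sd))))
  wt <- round(stats::rlnorm(n, dm$weight_meanlog, dm$weight_sdlog), 1)
  country <- sample(c("US", "JP", "FR", "DE", "GB", "IT", "ES", "CA",
                      "CN", "BR", "AU", "NL"), n, replace = TRUE,
                    prob = c(0.45, 0.12, 0.07, 0.07, 0.06, 0.05, 0.04,
                             0.04, 0.04, 0.03, 0.02, 0.01))
  outcome <- sample(config$outcome_model$codes, n, replace = TRUE,
                    prob = config$outcome_model$probs)
  fatal <- outcome == "DE"
  cancer <- sample(config$indication_mix$cancer, n, replace = TRUE,
                   prob = config$indication_mix$prob)
  cmb <- config$combo_model
  partner_present <- stats::runif(n) <
    ifelse(exposed, cmb$co_exposure_fraction, cmb$background_fraction)

  # --- reaction draws on the logistic reporting-odds scale ---------------
  eta <- matrix(stats::qlogis(cat$base_prob), n, p_pt, byrow = TRUE)
  sig <- config$injected_signals
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      col <- match(sig$pt[i], cat$pt)
      hit <- exposed & (sig$drug[i] == "*" | (!is.na(adc) & adc == sig$drug[i]))
      eta[hit, col] <- eta[hit, col] + log(sig$ror[i])
    }
  }
  ce <- config$cardiac_effects
  mult <- config$indication_mix$cardiac_odds_multiplier[
    match(cancer, config$indication_mix$cancer)]
  cardiac_shift <- ce$age_log_or * (age - ce$age_ref) +
    ce$male_log_or * (sex == "M") + ce$fatal_log_or * fatal + log(mult)
  eta[, is_cardiac_col] <- eta[, is_cardiac_col] + cardiac_shift
  for (pt_c in names(cmb$multipliers)) {
    col <- match(pt_c, cat$pt)
    hit <- exposed & partner_present
    eta[hit, col] <- eta[hit, col] + log(cmb$multipliers[[pt_c]])
  }
  draw <- matrix(stats::runif(n * p_pt), n, p_pt) < stats::plogis(eta)

  # per-PT counts of the pure model draws, before the reporting-process
  # adjustments below (co-reporting calibration, at-least-one-PT filler)
  pt_counts <- tibble::tibble(
    pt = cat$pt,
    n_exposed = colSums(draw[exposed, , drop = FALSE]),
    n_unexposed = colSums(draw[!exposed, , drop = FALSE])
  )

  cardiac_any <- rowSums(draw[, is_cardiac_col, drop = FALSE]) > 0
  # calibrated co-reporting fraction among cardiac reports
  if (!is.null(config$co_report_rate) && any(cardiac_any)) {
    keep_co <- stats::runif(n) < config$co_report_rate
    strip <- which(cardiac_any & !keep_co)
    draw[strip, !is_cardiac_col] <- FALSE
    need <- which(cardiac_any & keep_co &
                    rowSums(draw[, !is_cardiac_col, drop = FALSE]) == 0)
    if (length(need)) {
      extra <- resample(which(!is_cardiac_col), length(need), replace = TRUE,
                        prob = cat$base_prob[!is_cardiac_col])
      draw[cbind(need, extra)] <- TRUE
    }
  }
  # every report carries at least one reaction
  empty <- which(rowSums(draw) == 0)
  if (length(empty)) {
    filler <- resample(which(!is_cardiac_col), length(empty), replace = TRUE,
                       prob = cat$base_prob[!is_cardiac_col])
    draw[cbind(empty, filler)] <- TRUE
  }

  # --- onset and dates ----------------------------------------------------
  om <- config$onset_model
  meanlog <- ifelse(sex == "M", log(om$median_days_male),
                    log(om$median_days_female)) +
    ifelse(age > 65, log(om$age65_multiplier), 0)
  onset <- round(stats::rlnorm(n, meanlog, om$sdlog))
  w0 <- config$report_window[1]
  w1 <- config$report_window[2]
  start <- w0 + floor(stats::runif(n) *
                        (as.numeric(w1 - w0) - 120))
  event <- start + onset
  fda <- event + sample(3:90, n, replace = TRUE)
  fda <- pmin(fda, max(event) + 90)

  fmt <- function(d) format(d, "%Y%m%d")
  start_s <- fmt(start); event_s <- fmt(event); fda_s <- fmt(fda)

  # --- missingness (MCAR per field) --------------------------------------
  ms <- dm$missing
  mask <- function(rate) stats::runif(n) < rate
  age_rec <- ifelse(mask(ms$age), NA_real_, age)
  wt_rec <- ifelse(mask(ms$weight), NA_real_, wt)
  sex_rec <- ifelse(mask(ms$sex), NA_character_, sex)
  country_rec <- ifelse(mask(ms$country), NA_character_, country)
  event_rec <- ifelse(mask(ms$event_dt), NA_character_, event_s)
  start_rec <- ifelse(mask(ms$start_dt), NA_character_, start_s)
  outcome_rec <- ifelse(mask(ms$outcome), NA_character_, outcome)

  # --- corrupted dates ----------------------------------------------------
  datable <- which(!is.na(event_rec) & !is.na(start_rec))
  bad <- datable[stats::runif(length(datable)) < config$bad_date_rate]
  if (length(bad)) {
    swap <- bad[seq_along(bad) %% 2 == 0 & onset[bad] > 0]
    partial <- setdiff(bad, swap)
    tmp <- event_rec[swap]
    event_rec[swap] <- start_rec[swap]
    start_rec[swap] <- tmp
    start_rec[partial] <- substr(start_rec[partial], 1, 6)
  }

  # --- assemble long tables ----------------------------------------------
  pid <- seq_len(n) * 100L + 50L
  caseid <- seq_len(n)

  demo <- tibble::tibble(
    primaryid = pid, caseid = caseid, fda_dt = fda_s,
    event_dt = event_rec, sex = sex_rec, age = age_rec, wt = wt_rec,
    occr_country = country_rec
  )
  ps_drug <- ifelse(exposed, adc,
                    sample(.background_drug_pool, n, replace = TRUE))
  conco <- sample(.background_drug_pool, n, replace = TRUE)
  has_conco <- stats::runif(n) < 0.7
  drug <- dplyr::bind_rows(
    tibble::tibble(primaryid = pid, drugname = ps_drug, role_cod = "PS"),
    tibble::tibble(primaryid = pid[has_conco], drugname = conco[has_conco],
                   role_cod = "C"),
    tibble::tibble(primaryid = pid[partner_present],
                   drugname = cmb$partner, role_cod = "C")
  )
  hits <- which(draw, arr.ind = TRUE)
  reac <- tibble::tibble(primaryid = pid[hits[, 1]],
                         pt = cat$pt[hits[, 2]])
  reac <- reac[order(reac$primaryid, reac$pt), ]
  outc <- tibble::tibble(primaryid = pid, outc_cod = outcome_rec)
  outc <- outc[!is.na(outc$outc_cod), ]
  ther <- tibble::tibble(primaryid = pid, start_dt = start_rec)
  ther <- ther[!is.na(ther$start_dt), ]
  indi <- tibble::tibble(primaryid = pid, indi_pt = cancer)

  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, indi = indi)

  # --- near-duplicate clones under fresh caseids -------------------------
  n_cross <- floor(config$crossdup_rate * n)
  clone_of <- integer(0)
  if (n_cross > 0) {
    clone_of <- sample.int(n, n_cross)
    new_case <- n + seq_len(n_cross)
    new_pid <- new_case * 100L + 50L
    cl_demo <- demo[clone_of, ]
    cl_demo$primaryid <- new_pid
    cl_demo$caseid <- new_case
    cl_demo$fda_dt <- fmt(as.Date(cl_demo$fda_dt, "%Y%m%d") +
                            sample(1:30, n_cross, replace = TRUE))
    tables$demo <- dplyr::bind_rows(tables$demo, cl_demo)
    remap <- function(tbl) {
      sub <- tbl[tbl$primaryid %in% pid[clone_of], ]
      sub$primaryid <- new_pid[match(sub$primaryid, pid[clone_of])]
      dplyr::bind_rows(tbl, sub)
    }
    tables$drug <- remap(tables$drug); tables$reac <- remap(tables$reac)
    tables$outc <- remap(tables$outc); tables$ther <- remap(tables$ther)
    tables$indi <- remap(tables$indi)
  }

  # --- extra (stale) case versions ---------------------------------------
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    dup_of <- sample.int(n, n_dup)
    v_pid <- caseid[dup_of] * 100L + sample(10:49, n_dup, replace = TRUE)
    same_dt <- stats::runif(n_dup) < 0.3
    v_fda <- as.Date(fda_s[dup_of], "%Y%m%d") -
      ifelse(same_dt, 0, sample(10:200, n_dup, replace = TRUE))
    v_demo <- demo[dup_of, ]
    v_demo$primaryid <- v_pid
    v_demo$fda_dt <- fmt(v_fda)
    tables$demo <- dplyr::bind_rows(tables$demo, v_demo)
    remap2 <- function(tbl) {
      sub <- tbl[tbl$primaryid %in% pid[dup_of], ]
      map <- match(sub$primaryid, pid[dup_of])
      sub$primaryid <- v_pid[map]
      dplyr::bind_rows(tbl, sub)
    }
    tables$drug <- remap2(tables$drug); tables$reac <- remap2(tables$reac)
    tables$outc <- remap2(tables$outc); tables$ther <- remap2(tables$ther)
    tables$indi <- remap2(tables$indi)
  }
  tables <- lapply(tables, function(tbl) tbl[order(tbl$primaryid), ])

  # --- ground truth -------------------------------------------------------
  # expected unique-report count: clones are exact copies of their donors
  # on every screened field, so the count is the number of distinct
  # (sex, age, country, event date, reactions, drugs, indication) keys
  # among the n primary versions; only needed when duplication is on
  n_unique <- NA_integer_
  if (config$duplicate_rate > 0 || config$crossdup_rate > 0) {
    collapse_sets <- function(i, v) {
      sp <- split(v, i)
      out <- rep("", n)
      out[as.integer(names(sp))] <-
        vapply(sp, function(z) paste(sort(unique(z)), collapse = "|"),
               character(1))
      out
    }
    reac_sig <- collapse_sets(hits[, 1], cat$pt[hits[, 2]])
    di <- c(seq_len(n), which(has_conco), which(partner_present))
    dv <- normalize_drug(c(ps_drug, conco[has_conco],
                           rep(cmb$partner, sum(partner_present))))
    drug_set <- collapse_sets(di, dv)
    blank <- function(x) ifelse(is.na(x), "", as.character(x))
    sig_key <- paste(blank(sex_rec), blank(age_rec), blank(country_rec),
                     blank(event_rec), reac_sig, drug_set, cancer,
                     sep = "\x1f")
    n_unique <- length(unique(sig_key))
  }

  truth <- list(
    signals = sig,
    reports = tibble::tibble(
      primaryid = pid, caseid = caseid, exposed = exposed, adc_drug = adc,
      partner_present = partner_present, sex = sex, age = age,
      fatal = fatal, cancer = cancer, cardiac_any = cardiac_any,
      onset_days = onset
    ),
    pt_counts = pt_counts,
    n_unique_cases = n_unique,
    n_case_versions = nrow(tables$demo)
  )
  list(tables = tables, truth = truth, config = config)
}

#' Write simulated tables in the FAERS quarterly dialect
#'
#' @param tables Named list of tibbles as produced by
#'   [simulate_reports()]`$tables`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter, `"$"` by default.
#' @return Invisibly, the named vector of file paths.
#' @export
write_faers_tables <- function(tables, dir, delim = "$") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".txt"))
    readr::write_delim(tables[[nm]], p, delim = delim, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Configuration for the synthetic expression panel
#'
#' Negative-binomial count matrices over a panel of cancer types whose
#' pathway activity is known by construction: member genes of a linked
#' gene set have their log mean expression shifted by the configured
#' per-cancer activity level.
#'
#' @param cancers Named integer vector: samples per cancer type.
#' @param n_genes Number of genes in the universe.
#' @param n_sets,set_size Number and size of the random gene sets.
#' @param linked_pathways Named list: gene-set name to per-cancer activity
#'   (natural-log fold change applied to member genes). Defaults link a
#'   heat-shock-protein-binding set positively and an HGFR-signalling set
#'   negatively to the cardiac risk gradient of
#'   [default_indication_mix()].
#' @param noise_sd SD of per-gene-per-sample log-normal noise; 0 selects
#'   the noiseless limit in which the expected-count matrix is returned
#'   without negative-binomial sampling.
#' @param dispersion Negative-binomial size parameter.
#' @param base_meanlog_mean,base_meanlog_sd Distribution of per-gene
#'   baseline log means.
#' @param length_range Gene length range (bp).
#' @param seed Integer seed.
#' @return A validated `expr_sim_config` list.
#' @export
expr_sim_config <- function(cancers = NULL, n_genes = 400, n_sets = 11,
                            set_size = 25, linked_pathways = NULL,
                            noise_sd = 0.3, dispersion = 10,
                            base_meanlog_mean = 3, base_meanlog_sd = 1.2,
                            length_range = c(500, 10000), seed = 1L) {
  if (is.null(cancers)) {
    mix <- default_indication_mix()
    cancers <- stats::setNames(rep(12L, nrow(mix)), mix$cancer)
  }
  if (is.null(linked_pathways)) {
    mix <- default_indication_mix()
    grad <- stats::setNames(log(mix$cardiac_odds_multiplier), mix$cancer)
    grad <- grad[names(grad) %in% names(cancers)]
    linked_pathways <- list(
      heat_shock_protein_binding = grad,
      hgfr_signaling = -grad
    )
  }
  cfg <- structure(list(
    cancers = cancers, n_genes = as.integer(n_genes),
    n_sets = as.integer(n_sets), set_size = as.integer(set_size),
    linked_pathways = linked_pathways, noise_sd = noise_sd,
    dispersion = dispersion, base_meanlog_mean = base_meanlog_mean,
    base_meanlog_sd = base_meanlog_sd, length_range = length_range,
    seed = as.integer(seed)
  ), class = "expr_sim_config")
  if (any(cfg$cancers < 2)) stop("need at least 2 samples per cancer")
  if (cfg$set_size < 2 || cfg$set_size >= cfg$n_genes) {
    stop("set_size must be in [2, n_genes)")
  }
  if (cfg$noise_sd < 0 || cfg$dispersion <= 0) {
    stop("noise_sd must be >= 0 and dispersion > 0")
  }
  for (nm in names(cfg$linked_pathways)) {
    act <- cfg$linked_pathways[[nm]]
    if (!all(names(cfg$cancers) %in% names(act))) {
      stop("linked pathway '", nm, "' lacks activity for some cancers")
    }
  }
  cfg
}

#' Simulate a count matrix with known pathway activity
#'
#' @param config An `expr_sim_config`.
#' @return A list with `counts` (genes x samples), `gene_lengths` (named),
#'   `gene_sets` (named list; linked pathway names are included),
#'   `sample_cancers` (label per sample) and `truth` (the activity matrix
#'   and memberships).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  lengths <- stats::setNames(
    round(stats::runif(config$n_genes, config$length_range[1],
                       config$length_range[2])),
    genes
  )
  set_names <- names(config$linked_pathways)
  n_extra <- max(0, config$n_sets - length(set_names))
  set_names <- c(set_names, sprintf("random_pathway_%02d", seq_len(n_extra)))
  gene_sets <- stats::setNames(lapply(set_names, function(nm) {
    sample(genes, config$set_size)
  }), set_names)

  cancers <- names(config$cancers)
  sample_cancers <- rep(cancers, config$cancers)
  samples <- paste0(gsub("[^a-z0-9]", "_", sample_cancers), "_",
                    unlist(lapply(config$cancers, seq_len)))
  base <- stats::rnorm(config$n_genes, config$base_meanlog_mean,
                       config$base_meanlog_sd)
  shift <- matrix(0, config$n_genes, length(cancers),
                  dimnames = list(genes, cancers))
  for (nm in names(config$linked_pathways)) {
    act <- config$linked_pathways[[nm]][cancers]
    member <- genes %in% gene_sets[[nm]]
    shift[member, ] <- shift[member, ] +
      matrix(act, sum(member), length(cancers), byrow = TRUE)
  }
  mu <- exp(base + shift[, match(sample_cancers, cancers)] +
              matrix(stats::rnorm(config$n_genes * length(samples),
                                  0, config$noise_sd),
                     config$n_genes, length(samples)))
  # noise_sd = 0 is the noiseless limit: the expected-count matrix itself
  counts <- if (config$noise_sd == 0) {
    round(mu)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
           nrow = config$n_genes)
  }
  dimnames(counts) <- list(genes, samples)
  list(
    counts = counts,
    gene_lengths = lengths,
    gene_sets = gene_sets,
    sample_cancers = stats::setNames(sample_cancers, samples),
    truth = list(
      activity = do.call(rbind, lapply(config$linked_pathways,
                                       function(a) a[cancers])),
      linked = names(config$linked_pathways)
    )
  )
}
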