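test_that("ror_ci matches direct arithmetic on a worked table", {
  est <- ror_ci(30, 70, 100, 900)
  expect_equal(est$ror, 3.857, tolerance = 1e-3)
  expect_equal(est$ci_low, 2.399, tolerance = 1e-3)
  expect_equal(est$ci_high, 6.202, tolerance = 1e-3)
  orc <- oracle_ror(30, 70, 100, 900)
  expect_equal(est$ror, orc$ror, tolerance = 1e-12)
  expect_equal(est$ci_low, orc$ci_low, tolerance = 1e-12)
})

test_that("ror_ci obeys symmetry, reciprocity and scale laws", {
  for (k in c(1, 4, 25)) {
    est <- ror_ci(k, k, k, k)
    expect_equal(est$ror, 1)
    expect_lt(est$ci_low, 1)
    expect_gt(est$ci_high, 1)
  }
  e1 <- ror_ci(12, 7, 30, 200)
  e2 <- ror_ci(30, 200, 12, 7)
  expect_equal(e2$ror, 1 / e1$ror)
  expect_equal(e2$ci_low, 1 / e1$ci_high)
  expect_equal(e2$ci_high, 1 / e1$ci_low)
  # multiplying all cells by k keeps the point estimate, narrows the CI
  e4 <- ror_ci(12 * 4, 7 * 4, 30 * 4, 200 * 4)
  expect_equal(e4$ror, e1$ror)
  expect_lt(e4$ci_high / e4$ci_low, e1$ci_high / e1$ci_low)
})

test_that("zero cells are an explicit undefined condition, not a silent fix", {
  expect_warning(est <- ror_ci(0, 10, 5, 100), "zero cell")
  expect_true(is.na(est$ror))
  est2 <- ror_ci(0, 10, 5, 100, correction = TRUE)
  expect_true(is.finite(est2$ror))
  expect_error(ror_ci(-1, 1, 1, 1), ">= 0")
})

test_that("contingency tables count each report exactly once", {
  tab <- build_contingency(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
  tab2 <- build_contingency(rep(TRUE, 5), c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(tab2$c + tab2$d, 0)
  expect_error(build_contingency(c(TRUE, NA), c(TRUE, FALSE)), "total")
})

test_that("screen counts equal brute-force enumeration on a small database", {
  cfg <- sim_config(n_reports = 200, seed = 17, duplicate_rate = 0,
                    crossdup_rate = 0)
  sim <- simulate_reports(cfg)
  store <- tag_cardiac(as_faers_store(sim$tables), sim_term_map(cfg))
  res <- screen_signals(store, sim_term_map(cfg), cfg$target_drugs)

  # oracle: nested scan over reports and their raw reaction rows
  exposed_ids <- unique(sim$tables$drug$primaryid[
    sim$tables$drug$role_cod == "PS" &
      sim$tables$drug$drugname %in% cfg$target_drugs])
  cardiac_pts <- cfg$background_pt_catalog$pt[
    cfg$background_pt_catalog$soc == "cardiac disorders"]
  for (row in seq_len(nrow(res))) {
    pt <- res$pt[row]
    with_pt <- unique(sim$tables$reac$primaryid[sim$tables$reac$pt == pt])
    a <- b <- cc <- d <- 0
    for (id in store$demo$primaryid) {
      e <- id %in% exposed_ids
      v <- id %in% with_pt
      if (e && v) a <- a + 1 else if (e) b <- b + 1
      else if (v) cc <- cc + 1 else d <- d + 1
    }
    expect_equal(res$n_events[row], a)
    if (a > 0 && b > 0 && cc > 0 && d > 0) {
      orc <- oracle_ror(a, b, cc, d)
      expect_equal(res$ror[row], orc$ror, tolerance = 1e-12)
    } else {
      expect_true(is.na(res$ror[row]))   # zero cell: undefined estimate
    }
    expect_true(pt %in% cardiac_pts)
  }
})

test_that("the signal criterion needs three events and a CI floor above one", {
  # background of 2000 reports, 200 exposed
  n <- 2000
  demo <- mk_demo(1:n)
  exposed_ids <- 1:200
  drug <- tibble::tibble(primaryid = exposed_ids, drugname = "enhertu",
                         role_cod = "PS")
  reac <- dplyr::bind_rows(
    # strong but rare: 2 exposed events only
    tibble::tibble(primaryid = c(1, 2, 500, 501), pt = "cardiotoxicity"),
    # frequent but null: 10 exposed, 90 unexposed (ror ~ 1)
    tibble::tibble(primaryid = c(3:12, 300:389), pt = "cardiac failure"),
    # 5 exposed vs 9 unexposed: clear signal
    tibble::tibble(primaryid = c(13:17, 400:408), pt = "pericardial effusion")
  )
  store <- mk_store(demo, drug = drug, reac = reac)
  res <- screen_signals(store, test_term_map(), "enhertu")
  get <- function(pt) res[res$pt == pt, ]
  expect_false(get("cardiotoxicity")$is_signal)   # < 3 events
  expect_gt(get("cardiotoxicity")$ci_low, 1)      # despite a strong ROR
  expect_false(get("cardiac failure")$is_signal)  # CI floor below 1
  expect_lt(get("cardiac failure")$ci_low, 1)
  expect_true(get("pericardial effusion")$is_signal)
  # ranked by event count, then ROR
  expect_equal(res$pt[1], "cardiac failure")
})

test_that("screening is invariant to report order", {
  cfg <- sim_config(n_reports = 500, seed = 23, duplicate_rate = 0,
                    crossdup_rate = 0)
  sim <- simulate_reports(cfg)
  store <- as_faers_store(sim$tables)
  shuffled <- sim$tables
  set.seed(1)
  shuffled$demo <- shuffled$demo[sample(nrow(shuffled$demo)), ]
  shuffled$reac <- shuffled$reac[sample(nrow(shuffled$reac)), ]
  store2 <- as_faers_store(shuffled)
  r1 <- screen_signals(store, sim_term_map(cfg), cfg$target_drugs)
  r2 <- screen_signals(store2, sim_term_map(cfg), cfg$target_drugs)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("stratified screening partitions events and degenerates to the overall screen", {
  cfg <- sim_config(n_reports = 3000, seed = 31, duplicate_rate = 0,
                    crossdup_rate = 0,
                    demographic_model = utils::modifyList(
                      sim_config(n_reports = 1)$demographic_model,
                      list(missing = list(age = 0, weight = 0, sex = 0,
                                          country = 0, event_dt = 0.3,
                                          start_dt = 0.3, outcome = 0),
                           unk_sex_fraction = 0)
                    ))
  sim <- simulate_reports(cfg)
  store <- as_faers_store(sim$tables)
  tm <- sim_term_map(cfg)
  overall <- screen_signals(store, tm, cfg$target_drugs)
  strat <- stratified_signals(store, tm, cfg$target_drugs, by = "sex")
  # complementary strata conserve exposed event counts
  sums <- dplyr::summarise(dplyr::group_by(strat, .data$pt),
                           a = sum(.data$n_events), .groups = "drop")
  for (row in seq_len(nrow(sums))) {
    expect_equal(sums$a[row],
                 overall$n_events[overall$pt == sums$pt[row]])
  }
  # a single-stratum partition reproduces the overall screen
  allf <- sim$tables
  allf$demo$sex <- "F"
  strat_f <- stratified_signals(as_faers_store(allf), tm,
                                cfg$target_drugs, by = "sex")
  expect_equal(strat_f$n_events, overall$n_events)
  expect_equal(strat_f$ror, overall$ror)
})

test_that("combination screening warns when the partner is never co-reported", {
  demo <- mk_demo(1:50)
  drug <- tibble::tibble(primaryid = 1:10, drugname = "enhertu",
                         role_cod = "PS")
  reac <- tibble::tibble(primaryid = c(1:4, 21:24), pt = "cardiotoxicity")
  store <- mk_store(demo, drug = drug, reac = reac)
  expect_warning(
    res <- combination_signals(store, test_term_map(), "enhertu",
                               "dexamethasone"),
    "co-exposed"
  )
  expect_equal(nrow(res), 0)
})

test_that("a single-cancer database collapses the composite to the pooled ROR", {
  cfg <- sim_config(n_reports = 2000, seed = 37, duplicate_rate = 0,
                    crossdup_rate = 0,
                    indication_mix = tibble::tibble(
                      cancer = "breast cancer", prob = 1,
                      cardiac_odds_multiplier = 1))
  sim <- simulate_reports(cfg)
  store <- tag_cardiac(as_faers_store(sim$tables), sim_term_map(cfg))
  tm <- sim_term_map(cfg)
  sig <- screen_signals(store, tm, cfg$target_drugs)
  pts <- sig$pt[sig$is_signal]
  comp <- cancer_composite_ror(store, tm, cfg$target_drugs, signal_pts = pts)
  expect_equal(nrow(comp), 1)
  pooled <- ror_ci(build_contingency(is_ps_exposed(store, cfg$target_drugs),
                                     has_pt(store, pts)))
  expect_equal(comp$ror, pooled$ror)
  # a cancer with no cardiac events is flagged non-evaluable
  demo <- mk_demo(1:20)
  drug <- tibble::tibble(primaryid = 1:5, drugname = "enhertu",
                         role_cod = "PS")
  indi <- tibble::tibble(primaryid = 1:20, indi_pt = "lung cancer")
  reac <- tibble::tibble(primaryid = 6:8, pt = "nausea")
  st2 <- mk_store(demo, drug = drug, reac = reac, indi = indi)
  comp2 <- cancer_composite_ror(st2, test_term_map(), "enhertu",
                                signal_pts = "cardiotoxicity")
  expect_false(comp2$evaluable)
})
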