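test_that("the report generator is bit-reproducible from its seed", {
  cfg <- sim_config(n_reports = 300, seed = 42)
  s1 <- simulate_reports(cfg)
  s2 <- simulate_reports(cfg)
  expect_identical(s1$tables, s2$tables)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reports(sim_config(n_reports = 300, seed = 43))
  expect_false(identical(s1$tables$demo, s3$tables$demo))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_reports = 0), "positive")
  expect_error(
    sim_config(injected_signals = tibble::tibble(
      drug = "*", pt = "no such event", ror = 2)),
    "absent from the catalogue"
  )
  expect_error(
    sim_config(injected_signals = tibble::tibble(
      drug = "unknowndrug", pt = "cardiotoxicity", ror = 2)),
    "unknown drug"
  )
  expect_error(sim_config(duplicate_rate = 1.5), "rates")
})

test_that("duplicate case versions collapse back to the unique-case count", {
  cfg <- sim_config(n_reports = 1000, seed = 5, duplicate_rate = 0.2,
                    crossdup_rate = 0)
  sim <- simulate_reports(cfg)
  expect_equal(nrow(sim$tables$demo), 1200)
  store <- faers_deduplicate(as_faers_store(sim$tables))
  expect_equal(nrow(store$demo), sim$truth$n_unique_cases)
  expect_false(anyDuplicated(store$demo$caseid) > 0)
})

test_that("emitted 2x2 counts converge to the configured probabilities", {
  catalog <- tibble::tibble(
    pt = c("cardiotoxicity", "nausea", "fatigue"),
    soc = c("cardiac disorders", "gastrointestinal disorders",
            "general disorders and administration site conditions"),
    base_prob = c(0.01, 0.05, 0.05)
  )
  cfg <- sim_config(
    n_reports = 1e5, seed = 99, exposure_fraction = 0.1,
    background_pt_catalog = catalog,
    injected_signals = tibble::tibble(drug = "*", pt = "cardiotoxicity",
                                      ror = 5),
    cardiac_effects = list(age_log_or = 0, age_ref = 60, male_log_or = 0,
                           fatal_log_or = 0),
    indication_mix = dplyr::mutate(default_indication_mix(),
                                   cardiac_odds_multiplier = 1),
    combo_model = list(partner = "dexamethasone", co_exposure_fraction = 0,
                       background_fraction = 0, multipliers = numeric(0)),
    co_report_rate = NULL, duplicate_rate = 0, crossdup_rate = 0,
    bad_date_rate = 0
  )
  sim <- simulate_reports(cfg)
  n_exp <- sum(sim$truth$reports$exposed)
  n_un <- cfg$n_reports - n_exp
  counts <- sim$truth$pt_counts

  p0 <- 0.01
  p1 <- stats::plogis(stats::qlogis(p0) + log(5))
  for (row in seq_len(nrow(counts))) {
    pt <- counts$pt[row]
    p_e <- if (pt == "cardiotoxicity") p1 else catalog$base_prob[row]
    p_u <- catalog$base_prob[row]
    se_e <- sqrt(p_e * (1 - p_e) / n_exp)
    se_u <- sqrt(p_u * (1 - p_u) / n_un)
    expect_lt(abs(counts$n_exposed[row] / n_exp - p_e), 3 * se_e)
    expect_lt(abs(counts$n_unexposed[row] / n_un - p_u), 3 * se_u)
  }
})

test_that("the co-reporting calibration is recovered through the pipeline", {
  cfg <- sim_config(n_reports = 5e4, seed = 21, exposure_fraction = 0.5,
                    duplicate_rate = 0, crossdup_rate = 0)
  sim <- simulate_reports(cfg)
  store <- tag_cardiac(as_faers_store(sim$tables), sim_term_map(cfg))
  co <- co_reported_summary(store, sim_term_map(cfg))
  expect_lt(abs(co$fraction_co_reported - 0.65), 0.02)
})

test_that("expression simulation is reproducible and respects the noiseless limit", {
  cfg <- expr_sim_config(cancers = c(a = 3, b = 3), n_genes = 60,
                         n_sets = 3, set_size = 5,
                         linked_pathways = list(
                           s1 = c(a = 0.5, b = 0.5)
                         ),
                         noise_sd = 0, seed = 3)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1$counts, e2$counts)
  # equal activity in both cancers, no noise: identical mean scores
  tpm <- counts_to_tpm(e1$counts, e1$gene_lengths)
  sc <- ssgsea_scores(tpm, e1$gene_sets)
  act <- per_cancer_activity(sc, e1$sample_cancers)
  expect_equal(act["a", ], act["b", ], tolerance = 1e-12)
})

test_that("injected pathway activity is recovered as rank-concordant mean scores", {
  acts <- stats::setNames(seq(0, 0.9, length.out = 10),
                          paste0("c", 1:10))
  cfg <- expr_sim_config(cancers = stats::setNames(rep(10L, 10), names(acts)),
                         n_genes = 300, n_sets = 5, set_size = 20,
                         linked_pathways = list(linked = acts),
                         noise_sd = 0.3, seed = 8)
  ex <- simulate_expression(cfg)
  tpm <- counts_to_tpm(ex$counts, ex$gene_lengths)
  sc <- ssgsea_scores(tpm, ex$gene_sets)
  act <- per_cancer_activity(sc, ex$sample_cancers)
  rho <- stats::cor(act[names(acts), "linked"], acts, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("an unlinked gene set shows no association with the cancer index", {
  hits <- 0L
  for (seed in 1:10) {
    acts0 <- stats::setNames(rep(0, 8), paste0("c", 1:8))
    cfg <- expr_sim_config(cancers = stats::setNames(rep(8L, 8), names(acts0)),
                           n_genes = 200, n_sets = 2, set_size = 15,
                           linked_pathways = list(flat = acts0),
                           noise_sd = 0.3, seed = seed)
    ex <- simulate_expression(cfg)
    tpm <- counts_to_tpm(ex$counts, ex$gene_lengths)
    sc <- ssgsea_scores(tpm, ex$gene_sets)
    act <- per_cancer_activity(sc, ex$sample_cancers)
    ct <- spearman_cor_test(act[names(acts0), "flat"], seq_len(8))
    if (ct$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
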