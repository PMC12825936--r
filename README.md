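# cardiovigil

Pharmacovigilance signal detection for cardiac adverse events (cAEs) of
antibody-drug conjugates (ADCs), as an end-to-end, tested R pipeline.

Spontaneous-report databases such as FAERS are the main early-warning
system for rare drug toxicities. For a target drug set and an adverse
event, each report falls into one cell of the 2×2 table
(a: exposed with event, b: exposed without, c: unexposed with,
d: neither), and the **reporting odds ratio**

    ROR = (a / c) / (b / d),
    95% CI = exp( ln ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d) )

flags a *signal* when a PT has at least three exposed reports and the CI
lower bound exceeds one. Around that core statistic the package
implements the full study chain:

* **Report store** — reads FAERS-style `$`-delimited quarterly tables
  (DEMO/DRUG/REAC/OUTC/THER/INDI), deduplicates case versions (latest
  `FDA_DT`, then highest `PRIMARYID`, then a cross-field uniqueness
  screen), restricts to primary-suspect exposure, and resolves reaction
  terms against a PT→SOC map (a synthetic MedDRA-like fixture ships in
  `inst/extdata/`; the real dictionary is licensed).
* **Disproportionality** — PT-level screens, sex/age/drug/cancer
  subgroup screens, combination-therapy contrasts (e.g. ADCs alone vs
  with dexamethasone) and per-cancer composite cardiac RORs.
* **Cohort description** — Table-1-style summaries with
  per-characteristic denominators, chi-square/Fisher and Welch tests.
* **Time to onset** — `EVENT_DT − START_DT` with explicit exclusion of
  invalid dates, Kaplan–Meier onset curves (no censoring: 1 − ECDF),
  log-rank comparisons (permutation p at small n), milestone fractions.
* **Risk model** — crude and adjusted logistic odds ratios for age, sex
  and fatality; co-reported adverse-event summaries.
* **Pathway link** — counts→TPM, ssGSEA (rank-weighted, α = 0.25),
  per-cancer mean activity, and Spearman correlation of pathway activity
  with per-cancer composite cardiac RORs.
* **Synthetic generators** — `simulate_reports()` and
  `simulate_expression()` emit seeded FAERS-like databases and count
  matrices with known injected RORs, covariate effects, onset models,
  duplicates, bad dates and pathway activity, so every stage is testable
  by parameter recovery.

## Worked example

```r
library(cardiovigil)

cfg      <- sim_config(n_reports = 20000, seed = 7)   # synthetic FAERS stand-in
sim      <- simulate_reports(cfg)
term_map <- sim_term_map(cfg)

store <- as_faers_store(sim$tables)
store <- faers_deduplicate(store)
store <- tag_cardiac(store, term_map)

screen_signals(store, term_map, cfg$target_drugs)
#>   stratum pt                  n_events   ror ci_low ci_high is_signal
#> 1 overall cardiotoxicity            29 29.0  13.7     61.4  TRUE
#> 2 overall cardiac dysfunction       25 17.3   8.83    33.8  TRUE
#> 3 overall cardiac failure           21  2.57  1.58     4.19 TRUE
#> 4 overall cardiac disorder          18  1.64  0.988    2.71 FALSE
#> 5 overall atrial fibrillation       15  1.35  0.782    2.32 FALSE
```

Cardiotoxicity is recovered at ROR ≈ 29 (injected 30.99) with a CI well
above one; `cardiac disorder` misses the criterion because its CI floor
sits below one, even with 18 exposed reports. Onset and risk factors for
the primary-suspect cohort:

```r
adc    <- filter_primary_suspect(store, cfg$target_drugs)
onsets <- compute_onsets(adc)
onset_milestones(onsets$onsets$onset_days)
#>   cutoff_days n_within fraction
#> 1          90       36    0.562      # > half within three months
#> 2         300       57    0.891      # > 80% within ten months

flat <- flatten_reports(adc, cfg$target_drugs)
risk_or_table(flat, covariates = c("age", "sex"))
#>   term  estimate    or ci_low ci_high  p_value model    n_used
#> 1 age    0.00953 1.01   0.994   1.03  0.235    crude      1072
#> 2 sexM  -0.911   0.402  0.237   0.681 0.000709 crude      1938
#> 3 age    0.00977 1.01   0.994   1.03  0.233    adjusted   1040
#> 4 sexM  -0.886   0.412  0.203   0.835 0.0139   adjusted   1040
```

The adjusted male odds ratio of 0.41 recovers the generator's injected
protective effect (0.42): in this population male sex roughly halves the
odds that an ADC report is cardiac. See
`vignette("cardiovigil-methods")` for the model, the generator's design
and its calibration.

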