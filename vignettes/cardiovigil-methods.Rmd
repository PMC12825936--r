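---
title: "Methods: cardiac adverse-event signal detection for antibody-drug conjugates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac adverse-event signal detection for antibody-drug conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiovigil)
```

## The problem

Antibody-drug conjugates (ADCs) couple a tumour-targeting antibody to a
cytotoxic payload. Spontaneous-report databases such as FAERS accumulate
adverse-event reports for these drugs faster than trials can characterise
their rarer toxicities, and cardiac events — cardiotoxicity, cardiac
failure, ventricular dysfunction — are among the most consequential.
`cardiovigil` implements the complete analytical chain of a
disproportionality study of ADC-related cardiac adverse events: report
ingestion and deduplication, reporting-odds-ratio (ROR) signal screening
with subgroup, combination-therapy and per-cancer views, descriptive
cohort statistics, time-to-onset analysis, logistic risk modelling, and a
transcriptome arm that asks which biological pathways track the
per-cancer cardiac risk.

Because FAERS must be queried interactively and MedDRA is licensed, the
package ships a synthetic generator (`simulate_reports()`,
`simulate_expression()`) whose ground truth is known by construction.
Every stage of the pipeline is validated by parameter recovery against
that truth; real FAERS extracts in the quarterly ASCII dialect can be
substituted through `read_faers_tables()` without touching the analysis
code.

## Report store and deduplication

Reports are kept relationally, as FAERS distributes them: one DEMO row
per case version, with DRUG/REAC/OUTC/THER/INDI rows joined by
`primaryid`. Deduplication applies the FDA-style rule: among versions of
one `caseid`, keep the latest `FDA_DT`; among ties, the highest
`PRIMARYID`. A second screen then removes reports that are identical on
sex, age, country, event date, reactions, drugs and indications — the
cross-database near-duplicates that share no caseid — again keeping the
highest `primaryid`. Partial dates (`YYYY`, `YYYYMM`) are padded to the
first day of the period *for ordering only*; they are never treated as
day-precise elsewhere. The operation is idempotent, and missing submission
dates sort before everything.

## The ROR engine

For a target drug set $D$ (matched case-insensitively after stripping
punctuation, primary-suspect role only) and an event term $E$, every
report falls in exactly one cell of

|              | event $E$ | no event |
|--------------|-----------|----------|
| exposed      | $a$       | $b$      |
| unexposed    | $c$       | $d$      |

and the reporting odds ratio is $\mathrm{ROR} = (a/c)/(b/d)$ with the
Woolf log-scale interval
$\exp\{\ln \mathrm{ROR} \pm z\sqrt{1/a + 1/b + 1/c + 1/d}\}$.
A cardiac preferred term is a *signal* when it has at least three exposed
reports and the 95% CI lower bound exceeds one. Zero cells leave the
estimate undefined: the default surfaces an explicit `NA` with a warning
rather than silently applying a continuity correction (a Haldane 0.5
flag exists for exploratory use). The counting unit is the report: a
report with two cardiac PTs contributes once to each PT's table and once
to any composite event.

Subgroup screens (`stratified_signals()`) restrict both the exposed set
and the background to the stratum for sex, age group (cut at 65 years)
and cancer indication; per-drug "strata" are not a partition of the
database, so they vary the exposure definition against the full
background instead. Combination screens
(`combination_signals()`) contrast exposure *without* a partner drug
against exposure *with* it (partner matched in any role), both against
the full background — the design behind the dexamethasone comparison.
Per-cancer composites (`cancer_composite_ror()`) use "any
signal-positive cardiac PT" as the event and flag cancers with fewer
than three composite events as non-evaluable instead of reporting an
unstable ROR.

## Descriptive tables and tests

`describe_cohort()` contrasts cardiac reports with other reports.
Categorical rows report $n$ (%) with the *per-characteristic non-missing
group size* as the denominator — the convention forced by the internal
arithmetic of published Table-1-style summaries, where the outcome and
fatality rows of one group visibly use different denominators. Reports
missing a characteristic are excluded from that characteristic only, and
the missing counts are emitted alongside. Weight bands are fixed at
<80, 80–100 (inclusive) and >100 kg. A single primary outcome per report
is chosen by severity (DE > LT > HO > DS > CA > RI > OT); fatality means
any death outcome.

Counts are compared by Pearson's chi-square without continuity
correction, switching to Fisher's exact test when any expected cell is
below five (exact for 2×2, simulated p for larger tables; the simulation
uses a fixed internal RNG stream so results are reproducible and
order-invariant). The continuous age comparison uses Welch's t-test —
published FAERS descriptive tables typically name only
chi-square/Fisher while still reporting a p-value for mean age, which
implies a two-sample location test, and Welch is the robust default; a
Mann–Whitney alternative is available.

## Time to onset

Onset is `EVENT_DT − START_DT` in days. Only day-precise, valid calendar
dates qualify: missing dates, partial dates and impossible dates are
excluded (tallied by reason), as are strictly negative intervals, which
are data-entry errors; same-day onsets are retained. With every included
report having experienced the event and no censoring, the Kaplan–Meier
event-free curve reduces to one minus the empirical CDF and the median
is the smallest time where the curve reaches 0.5 (a 1e-9 tolerance
guards the crossing against float accumulation). Milestones are reported
at 90 and 300 days — three and ten months at the fixed 30-day month used
throughout.

Group comparisons use the log-rank test (`survival::survdiff`). The
chi-square reference is unreliable in very small groups: we measured
discrepancies of up to ~0.08 between the asymptotic and exact
permutation p at eight samples per group. `logrank_compare()` therefore
reports a permutation p-value (default $10^4$ permutations of the group
labels) whenever the smallest group has ten or fewer samples, and the
asymptotic p otherwise; both modes can be forced.

## Logistic risk model

`fit_logistic()` regresses the cardiac indicator on age (years,
continuous), sex (female reference; unknown excluded) and fatality
(nonfatal reference) by maximum likelihood, on the complete cases of the
requested covariate set, reporting Wald 95% intervals. Wald intervals
(not profile likelihood) keep the univariate binary-covariate fit
algebraically identical to the 2×2 cross-product odds ratio, which the
tests exploit as an oracle. Fatality as an *exposure* of a cardiac
*outcome* mirrors the published forest-plot design but is temporally
downstream of the event — the documentation flags this, and so should
any interpretation. Perfect separation is detected (runaway coefficients
or fitted probabilities at the boundary) and flagged as non-converged
rather than reported as a finite OR.

## The transcriptome arm

Counts become TPM by dividing by gene length and rescaling each sample
to $10^6$. ssGSEA scores each sample against each gene set using the
rank-weighted running-sum definition: genes ranked by expression within
the sample (average ranks on ties), the list walked in
decreasing-expression order, in-set steps weighted $r^{\alpha}$ with
$\alpha = 0.25$ and normalised to sum to one over the set, out-of-set
steps uniform; the enrichment score is the sum over positions of the
difference in cumulative sums, and the whole score matrix is divided by
its range (both $\alpha$ and the normalisation are arguments — the
upstream convention names the package but not its settings, so both
modes are exposed). Scores depend on the data only through within-sample
ranks, hence are invariant to monotone transforms, sequencing depth and
gene order.

Per-cancer activity is the arithmetic mean score over that cancer's
samples. The link to pharmacovigilance is Spearman rank correlation
between per-cancer composite cardiac RORs and per-cancer activity, with
the t-approximation p-value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df, two-sided, ties handled by
average ranks. Pathways are reported unadjusted, as is conventional for
this screen; a Benjamini–Hochberg column is available but off by
default.

## The synthetic generator

`sim_config()` encodes the study conditions: a 2019–2023 reporting
window; nine target ADCs at a 10% exposure fraction; a catalogue of 13
cardiac and 13 non-cardiac PTs with background reporting probabilities;
injected class-level cardiac signals at the reported ROR magnitudes
(cardiotoxicity 30.99 down to pericardial effusion 1.39); an 80% female,
age 60 ± 13.5 population with breast cancer dominating the indication
mix; cardiac covariate effects at FAERS-realistic adjusted-odds-ratio
magnitudes (age 1.013/year, male 0.42, fatal 0.75) plus a per-cancer odds
gradient (bile duct highest, bladder lowest); dexamethasone co-exposure
in 20% of exposed reports with protective multipliers (cardiac failure
0.27, pericardial effusion 0.34, cardiomyopathy 0.35); 20% duplicated
case versions, 1% caseid clones, 5% corrupted dates, and per-field
missingness at Table-1-like rates.

Signals are parameterised directly on the reporting-odds scale — the
log-odds of a PT is shifted by $\log(\mathrm{ROR})$ under exposure — so
that parameter recovery is a first-class test. Three deliberate
compromises are documented because they shape what passing tests mean:

* **Non-collapsibility.** Cardiac covariate effects act on the
  *conditional* logit, so the marginal 2×2 ROR of a common event is
  attenuated relative to the injected conditional value. Coverage and
  effect-recovery experiments therefore zero the covariate effects (and
  the logistic-recovery experiment uses a single cardiac PT, making the
  cardiac indicator exactly logistic in the covariates); the default
  study configuration keeps all effects on.
* **The at-least-one-reaction filler.** Reports whose draws produce no
  PT receive one filler non-cardiac PT sampled by base probability, so
  non-cardiac marginals exceed their nominal probabilities; cardiac
  counts are never touched. `truth$pt_counts` records the pre-adjustment
  draws, so the law-of-large-numbers check remains exact.
* **Co-reporting calibration.** To make "65% of cardiac reports carry
  another event" directly configurable, non-cardiac PTs are stripped or
  topped up on cardiac reports after the draws. In signal-bearing
  configurations cardiac status correlates with exposure, so this can
  bias *non-cardiac* RORs; experiments that measure generator
  calibration disable it.

Onset days are log-normal. The emulated onset pattern — female median 98
days, male 28, longer onsets above 65, over half of onsets within 3
months and over 80% within 10 — cannot all hold in one mixture (a female
median of 98 days in a ~90% female cardiac cohort pins the ≤90-day
fraction at ~0.50). The defaults were calibrated analytically, once,
before any test was run: female median 85 days, male 28, `sdlog` 1.0,
×1.2 above 65 years. This preserves the sex and age contrasts and the
cumulative-onset shape with margin; the sex-difference power experiment
configures the 98/28 medians explicitly. With `noise_sd = 0` the
expression generator returns the rounded expected-count matrix — the
noiseless limit needed for exact symmetry checks that negative-binomial
sampling would otherwise blur.

## Problem sizes and reproducibility

The default database is 50 000 reports (≈5 000 ADC-exposed — the same
exposed-to-background proportion as the roughly 27 000 ADC reports that
a 2019–2023 FAERS query yields against the full database, at desk
scale) and the default expression panel is
12 cancers × 12 samples × 400 genes. Monte-Carlo experiments in the test
suite use 100–200 seeded replicates per condition. Every random draw in
the generators flows from a single integer seed; identical seed and
configuration give byte-identical tables.

## Limitations

The generator is missing-completely-at-random, has no reporting-culture
or country effects, no narrative text, no informative missingness, and
its indication list is a 12-cancer condensation of the several dozen
indications ADCs carry in practice. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated generative model, not robustness to the
biases of real spontaneous-report data — stimulated reporting,
under-reporting, confounding by indication — which no desk-scale
simulation can certify. Bayesian disproportionality statistics (BCPNN,
EBGM), PRR, competing-risk onset models and multiplicity correction
across PTs are intentionally out of scope.
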