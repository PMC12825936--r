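# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's code paths.

# direct-arithmetic reporting odds ratio with Woolf interval
oracle_ror <- function(a, b, c, d, z = 1.96) {
  ror <- (a / c) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror,
       ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se))
}

# two-group log-rank chi-square computed from first principles:
# at each event time, observed minus hypergeometric-expected events in
# group 1, with the usual variance term
oracle_logrank_chisq <- function(time, grp1) {
  ut <- sort(unique(time))
  u <- 0; v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & grp1)
    d_t <- sum(time == t)
    d1_t <- sum(time == t & grp1)
    e1_t <- d_t * n1_t / n_t
    u <- u + (d1_t - e1_t)
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  u^2 / v
}

oracle_logrank_perm_p <- function(time, grp1, n_perm) {
  obs <- oracle_logrank_chisq(time, grp1)
  n1 <- sum(grp1)
  n <- length(time)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- logical(n)
    g[sample.int(n, n1)] <- TRUE
    if (oracle_logrank_chisq(time, g) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# classical Spearman formula for tie-free vectors
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p for a
# 2x2 table with fixed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_min <- max(0, r1 + c1 - n)
  a_max <- min(r1, c1)
  probs <- vapply(a_min:a_max, function(a) {
    stats::dhyper(a, c1, n - c1, r1)
  }, numeric(1))
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# compact builder for tiny in-memory stores
mk_store <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                     ther = NULL, indi = NULL) {
  as_faers_store(list(demo = demo, drug = drug, reac = reac,
                      outc = outc, ther = ther, indi = indi))
}

mk_demo <- function(primaryid, caseid = primaryid, fda_dt = "20230101",
                    event_dt = NA, sex = "F", age = 60, wt = 70,
                    occr_country = "US") {
  tibble::tibble(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                 event_dt = event_dt, sex = sex, age = age, wt = wt,
                 occr_country = occr_country)
}

test_term_map <- function() {
  tibble::tibble(
    pt = c("cardiotoxicity", "cardiac failure", "pericardial effusion",
           "nausea", "diarrhoea", "fatigue"),
    soc = c("cardiac disorders", "cardiac disorders", "cardiac disorders",
            "gastrointestinal disorders", "gastrointestinal disorders",
            "general disorders and administration site conditions")
  )
}
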