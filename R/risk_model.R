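#' Logistic regression for cardiac-event risk factors
#'
#' Fits a binomial GLM (maximum likelihood via iteratively reweighted
#' least squares) of the cardiac-event indicator on the requested
#' covariates, on the complete cases for that covariate set. Covariate
#' coding follows the reporting convention of the study design: age in
#' years (continuous), sex with female as reference (reports with unknown
#' sex are excluded), fatality with nonfatal as reference. Odds ratios use
#' Wald 95% confidence intervals, which keeps the univariate
#' binary-covariate fit algebraically identical to the 2x2 cross-product
#' odds ratio.
#'
#' Fatality is modelled as an exposure covariate of the cardiac outcome,
#' mirroring the forest-plot design this reproduces, even though a fatal
#' outcome is temporally downstream of the event; interpret accordingly.
#'
#' @param flat One-row-per-report tibble from [flatten_reports()] with a
#'   `has_cardiac` column (typically restricted to the target-drug
#'   cohort).
#' @param covariates Subset of `c("age", "sex", "fatality")`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return A tibble with one row per model term (`term`, `estimate` on the
#'   log-odds scale, `or`, `ci_low`, `ci_high`, `p_value`); attributes
#'   `n_used`, `converged`, `log_likelihood`.
#' @export
fit_logistic <- function(flat, covariates = c("age", "sex", "fatality"),
                         max_iter = 25, tol = 1e-8) {
  covariates <- match.arg(covariates, c("age", "sex", "fatality"),
                          several.ok = TRUE)
  stopifnot("has_cardiac" %in% names(flat))
  d <- tibble::tibble(y = as.integer(flat$has_cardiac))
  if ("age" %in% covariates) d$age <- flat$age_years
  if ("sex" %in% covariates) {
    sx <- toupper(flat$sex)
    sx[!sx %in% c("F", "M")] <- NA
    d$sex <- factor(sx, levels = c("F", "M"))
  }
  if ("fatality" %in% covariates) {
    d$fatality <- factor(ifelse(is.na(flat$fatal), NA_character_,
                                ifelse(flat$fatal, "fatal", "nonfatal")),
                         levels = c("nonfatal", "fatal"))
  }
  cc <- stats::complete.cases(d)
  d <- d[cc, ]
  if (nrow(d) == 0) stop("no complete cases for the requested covariates")
  fit <- stats::glm(
    y ~ ., family = stats::binomial(), data = d,
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  )
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- any(abs(est[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  converged <- fit$converged && !separated
  if (!converged) {
    warning("logistic fit flagged non-converged",
            if (separated) " (possible perfect separation)")
  }
  z <- est / se
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    or = exp(unname(est)),
    ci_low = exp(unname(est - 1.96 * se)),
    ci_high = exp(unname(est + 1.96 * se)),
    p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
  attr(out, "n_used") <- nrow(d)
  attr(out, "converged") <- converged
  attr(out, "log_likelihood") <- as.numeric(stats::logLik(fit))
  out
}

#' Crude and adjusted odds ratios for cardiac events
#'
#' Runs one univariate logistic fit per covariate (crude odds ratios) and
#' one joint fit (adjusted odds ratios), the layout behind a standard
#' risk-factor forest plot. Complete-case handling is per model.
#'
#' @inheritParams fit_logistic
#' @return A tibble of non-intercept terms with a `model` column
#'   (`"crude"` or `"adjusted"`) and an `n_used` column.
#' @export
risk_or_table <- function(flat, covariates = c("age", "sex", "fatality")) {
  crude <- purrr::map_dfr(covariates, function(cv) {
    f <- fit_logistic(flat, cv)
    n_f <- attr(f, "n_used")
    f <- f[f$term != "(Intercept)", ]
    f$model <- "crude"
    f$n_used <- n_f
    f
  })
  adj <- fit_logistic(flat, covariates)
  n_adj <- attr(adj, "n_used")
  adj <- adj[adj$term != "(Intercept)", ]
  adj$model <- "adjusted"
  adj$n_used <- n_adj
  dplyr::bind_rows(crude, adj)
}

#' Co-reported adverse events of cardiac reports
#'
#' Among cardiac-tagged reports, summarises the non-cardiac reactions
#' reported alongside: the fraction of cardiac reports with at least one
#' co-reported event, the distribution of co-reported PTs by system organ
#' class, and the most frequent co-reported PTs.
#'
#' @param store A `faers_store` tagged with [tag_cardiac()].
#' @param term_map PT to SOC map.
#' @param top_k Number of top PTs to return.
#' @return List with `n_cardiac`, `n_with_co`, `fraction_co_reported`,
#'   `by_soc` (tibble `soc`, `n`, `pct`) and `top_pts` (tibble `pt`, `n`).
#' @export
co_reported_summary <- function(store, term_map, top_k = 10) {
  stopifnot("has_cardiac" %in% names(store$demo))
  card_ids <- store$demo$primaryid[store$demo$has_cardiac]
  rx <- store$reac[store$reac$primaryid %in% card_ids, ]
  rx$pt_norm <- normalize_term(rx$pt)
  rx <- rx[!duplicated(rx[c("primaryid", "pt_norm")]), ]
  cardiac <- cardiac_pt_set(term_map)
  co <- rx[!rx$pt_norm %in% cardiac, ]

  tm <- tibble::tibble(pt_norm = normalize_term(term_map$pt),
                       soc = normalize_term(term_map$soc))
  co <- dplyr::left_join(co, tm, by = "pt_norm")
  co$soc[is.na(co$soc)] <- "(unmapped)"

  by_soc <- dplyr::count(co, .data$soc, sort = TRUE, name = "n")
  by_soc$pct <- tabulate_percent(by_soc$n)
  top_pts <- utils::head(dplyr::count(co, pt = .data$pt_norm, sort = TRUE,
                                      name = "n"), top_k)
  n_with <- length(unique(co$primaryid))
  list(
    n_cardiac = length(card_ids),
    n_with_co = n_with,
    fraction_co_reported = if (length(card_ids)) n_with / length(card_ids)
                           else NA_real_,
    by_soc = by_soc,
    top_pts = top_pts
  )
}
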