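#' Time-to-onset samples for cardiac reports
#'
#' Onset is the interval in days between the adverse-event date
#' (`EVENT_DT`) and the start of therapy (`START_DT`). Only reports with
#' both dates fully recorded at day precision enter the analysis:
#' reports with a missing date are excluded as `missing_date`, partial or
#' non-calendar dates as `inaccurate_date`, and strictly negative intervals
#' (event before start, a data-entry error) as `event_before_start`.
#' Same-day onsets (0 days) are retained.
#'
#' @param store A `faers_store` tagged with [tag_cardiac()].
#' @param age_cutoff Elderly cutoff used for the `age_group` covariate.
#' @return A list with `onsets` (tibble: `primaryid`, `onset_days`, `sex`,
#'   `age_group`, `cancer`) and `exclusions` (tibble: `reason`, `n`).
#'   Included plus excluded rows equal the cardiac report count.
#' @export
compute_onsets <- function(store, age_cutoff = 65) {
  stopifnot(inherits(store, "faers_store"))
  if (!"has_cardiac" %in% names(store$demo)) {
    stop("store must be tagged with tag_cardiac() first")
  }
  flat <- flatten_reports(store)
  flat <- flat[flat$has_cardiac, ]

  ev_raw <- flat$event_dt
  st_raw <- flat$start_dt
  missing <- is.na(ev_raw) | ev_raw == "" | is.na(st_raw) | st_raw == ""
  ev <- parse_full_date(ev_raw)
  st <- parse_full_date(st_raw)
  inaccurate <- !missing & (is.na(ev) | is.na(st))
  days <- as.numeric(ev - st)
  negative <- !missing & !inaccurate & days < 0
  ok <- !missing & !inaccurate & !negative

  onsets <- tibble::tibble(
    primaryid = flat$primaryid[ok],
    onset_days = days[ok],
    sex = toupper(flat$sex[ok]),
    age_group = ifelse(is.na(flat$age_years[ok]), NA_character_,
                       ifelse(flat$age_years[ok] > age_cutoff,
                              paste0(">", age_cutoff),
                              paste0("<=", age_cutoff))),
    cancer = flat$indication[ok]
  )
  list(
    onsets = onsets,
    exclusions = tibble::tibble(
      reason = c("missing_date", "inaccurate_date", "event_before_start"),
      n = c(sum(missing), sum(inaccurate), sum(negative))
    )
  )
}

#' Kaplan-Meier estimate of the onset curve
#'
#' With every report experiencing the event and no censoring, the
#' Kaplan-Meier event-free probability reduces to one minus the empirical
#' CDF of onset time, and the cumulative-onset curve is its complement.
#' The median is the smallest time at which the event-free probability
#' drops to 0.5 or below.
#'
#' @param onset_days Non-negative numeric vector of onset times (days).
#' @return A `km_onset` list: `time`, `surv` (event-free probability),
#'   `cum_onset`, `n_risk`, `median`, `n`.
#' @export
km_estimate <- function(onset_days) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (length(onset_days) == 0) stop("no onset samples to estimate from")
  stopifnot(all(onset_days >= 0))
  fit <- survival::survfit(
    survival::Surv(onset_days, rep(1L, length(onset_days))) ~ 1
  )
  structure(
    list(
      time = fit$time,
      surv = fit$surv,
      cum_onset = 1 - fit$surv,
      n_risk = fit$n.risk,
      # small tolerance so accumulated float error in the KM product
      # cannot shift the median off the order-statistic definition
      median = min(fit$time[fit$surv <= 0.5 + 1e-9]),
      n = length(onset_days)
    ),
    class = "km_onset"
  )
}

#' @export
print.km_onset <- function(x, ...) {
  cat("<km_onset> n = ", x$n, ", median = ", x$median, " days\n", sep = "")
  invisible(x)
}

# internal: log-rank chi-square for onset data (no censoring), vectorised
# enough to drive the permutation p-value at small n
logrank_stat <- function(time, group) {
  sd <- survival::survdiff(
    survival::Surv(time, rep(1L, length(time))) ~ group
  )
  unname(sd$chisq)
}

#' Log-rank comparison of onset-time groups
#'
#' Standard log-rank test on `k` groups (df = k - 1) with per-group
#' Kaplan-Meier medians. The chi-square reference distribution is
#' unreliable at very small group sizes, so when the smallest group has
#' `perm_cutoff` samples or fewer (and `p_method = "auto"`) the p-value is
#' instead taken from the permutation distribution of the log-rank
#' statistic under random relabelling.
#'
#' @param onset_days Numeric vector of onset times.
#' @param group Group labels (NA dropped); groups left empty after NA
#'   removal are dropped with a warning and at least two groups must
#'   remain.
#' @param p_method `"auto"`, `"asymptotic"` or `"permutation"`.
#' @param perm_cutoff Smallest-group size at or below which `"auto"`
#'   switches to the permutation p-value.
#' @param n_perm Number of permutations.
#' @return List with `statistic`, `df`, `p_value`, `p_method` and
#'   `medians` (tibble: `group`, `n`, `median_days`).
#' @export
logrank_compare <- function(onset_days, group, p_method = "auto",
                            perm_cutoff = 10, n_perm = 1e4) {
  p_method <- match.arg(p_method, c("auto", "asymptotic", "permutation"))
  keep <- !is.na(onset_days) & !is.na(group)
  if (any(!keep)) warning(sum(!keep), " sample(s) with missing data dropped")
  time <- onset_days[keep]
  group <- as.character(group[keep])
  k <- length(unique(group))
  if (k < 2) stop("need at least two non-empty groups")

  obs <- logrank_stat(time, group)
  min_n <- min(table(group))
  use_perm <- p_method == "permutation" ||
    (p_method == "auto" && min_n <= perm_cutoff)
  if (use_perm) {
    perm <- vapply(seq_len(n_perm),
                   function(i) logrank_stat(time, sample(group)),
                   numeric(1))
    p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
    p_method <- "permutation"
  } else {
    p <- stats::pchisq(obs, df = k - 1, lower.tail = FALSE)
    p_method <- "asymptotic"
  }
  medians <- purrr::map_dfr(sort(unique(group)), function(g) {
    in_g <- group == g
    tibble::tibble(group = g, n = sum(in_g),
                   median_days = km_estimate(time[in_g])$median)
  })
  list(statistic = obs, df = k - 1, p_value = p, p_method = p_method,
       medians = medians)
}

#' Fraction of onsets within milestone windows
#'
#' Reports the exact empirical fractions of onsets within the given
#' cutoffs; defaults are 90 and 300 days (three and ten months at the
#' fixed 30-day month used throughout).
#'
#' @param onset_days Numeric vector of onset times.
#' @param cutoffs Days defining the milestone windows.
#' @return A tibble with `cutoff_days`, `n_within`, `fraction`.
#' @export
onset_milestones <- function(onset_days, cutoffs = c(90, 300)) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (length(onset_days) == 0) stop("no onset samples")
  tibble::tibble(
    cutoff_days = cutoffs,
    n_within = vapply(cutoffs, function(ct) sum(onset_days <= ct), integer(1)),
    fraction = vapply(cutoffs, function(ct) mean(onset_days <= ct), numeric(1))
  )
}
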