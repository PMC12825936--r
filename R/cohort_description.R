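#' Percentages from a vector of counts
#'
#' The denominator is the sum of the supplied counts, i.e. the reports
#' with that characteristic recorded in the group (missing values are
#' excluded per characteristic before counting).
#'
#' @param counts Non-negative numeric vector.
#' @param digits Decimal places for rounding (2, the precision used in
#'   published descriptive tables).
#' @return Numeric vector of percentages summing to 100 up to rounding.
#' @export
tabulate_percent <- function(counts, digits = 2) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) return(rep(NA_real_, length(counts)))
  round(100 * counts / sum(counts), digits)
}

#' Chi-square or Fisher comparison of categorical counts
#'
#' Pearson's chi-square without continuity correction is used unless any
#' expected cell count is below 5, in which case Fisher's exact test is
#' used (exact for 2x2; simulated p-value for larger tables).
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @param fisher_threshold Expected-count threshold that triggers Fisher.
#' @param B Monte-Carlo replicates for simulated Fisher p on large tables.
#' @return List with `statistic` (NA for Fisher), `p_value`, `test`.
#' @export
compare_categorical <- function(tab, fisher_threshold = 5, B = 1e4) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2, ncol(tab) >= 2, all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate table (zero margin); no test performed")
    return(list(statistic = NA_real_, p_value = NA_real_,
                test = "degenerate"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < fisher_threshold)) {
    ft <- if (all(dim(tab) == c(2, 2))) {
      stats::fisher.test(tab)
    } else {
      # the simulated p draws from a fixed internal RNG stream so the
      # result is reproducible and independent of caller state
      old_seed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit({
        if (!is.null(old_seed)) {
          assign(".Random.seed", old_seed, envir = globalenv())
        }
      }, add = TRUE)
      set.seed(190101)
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
    }
    list(statistic = NA_real_, p_value = ft$p.value, test = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value,
         test = "chi-square")
  }
}

#' Two-sample comparison of a continuous characteristic
#'
#' Welch's t-test by default (the robust two-sample location default);
#' a Mann-Whitney alternative is available.
#'
#' @param x,y Numeric vectors (missing values dropped); each group needs
#'   at least two non-missing values.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return List with `statistic`, `p_value`, `test`, and per-group `mean`
#'   and `sd`.
#' @export
compare_continuous <- function(x, y, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    warning("each group needs >= 2 non-missing values; no test performed")
    return(list(statistic = NA_real_, p_value = NA_real_,
                test = "degenerate",
                mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y))))
  }
  res <- if (method == "welch") {
    tryCatch(stats::t.test(x, y), error = function(e) NULL)
  } else {
    stats::wilcox.test(x, y, exact = FALSE)
  }
  if (is.null(res)) {
    # both groups constant: t undefined; identical means carry no evidence
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0, test = "welch-t",
                mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y))))
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       test = if (method == "welch") "welch-t" else "wilcoxon",
       mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)))
}

# weight bands used in the descriptive table: <80, 80-100 inclusive, >100
weight_band <- function(wt) {
  ifelse(is.na(wt), NA_character_,
         ifelse(wt < 80, "<80", ifelse(wt <= 100, "80-100", ">100")))
}

#' Table-1-style cohort description
#'
#' Compares cardiac-event reports with other-event reports characteristic
#' by characteristic. Categorical characteristics report `n` and percent
#' with the per-characteristic non-missing group size as denominator;
#' continuous characteristics report mean and SD. Reports with a missing
#' value for a characteristic are excluded from that characteristic only,
#' and the missing counts are emitted alongside.
#'
#' @param flat One-row-per-report tibble from [flatten_reports()] with a
#'   `has_cardiac` column.
#' @param characteristics Subset of `c("sex", "age", "age_group",
#'   "weight_band", "country", "outcome", "fatality", "indication",
#'   "drug")`.
#' @param age_cutoff Elderly cutoff in years for `age_group`.
#' @return A tibble with one row per characteristic level (or one row per
#'   continuous characteristic) and columns for counts, percentages,
#'   means/SDs, missing counts, `p_value` and `test`.
#' @export
describe_cohort <- function(flat,
                            characteristics = c("sex", "age", "age_group",
                                                "weight_band", "outcome",
                                                "fatality"),
                            age_cutoff = 65) {
  supported <- c("sex", "age", "age_group", "weight_band", "country",
                 "outcome", "fatality", "indication", "drug")
  bad <- setdiff(characteristics, supported)
  if (length(bad)) {
    stop("unknown characteristic(s): ", paste(bad, collapse = ", "))
  }
  stopifnot("has_cardiac" %in% names(flat))
  grp <- flat$has_cardiac
  stopifnot(!anyNA(grp))

  value_of <- function(ch) {
    switch(ch,
      sex = {
        v <- toupper(flat$sex)
        v[!v %in% c("F", "M", "UNK")] <- NA
        v
      },
      age = flat$age_years,
      age_group = ifelse(is.na(flat$age_years), NA_character_,
                         ifelse(flat$age_years > age_cutoff,
                                paste0(">", age_cutoff),
                                paste0("<=", age_cutoff))),
      weight_band = weight_band(flat$weight_kg),
      country = flat$country,
      outcome = flat$outcome,
      fatality = ifelse(is.na(flat$fatal), NA_character_,
                        ifelse(flat$fatal, "Fatal", "Nonfatal")),
      indication = flat$indication,
      drug = flat$adc_drug
    )
  }

  rows <- purrr::map_dfr(characteristics, function(ch) {
    v <- value_of(ch)
    miss1 <- sum(is.na(v) & grp)
    miss2 <- sum(is.na(v) & !grp)
    if (is.numeric(v)) {
      cmp <- if (sum(!is.na(v[grp])) >= 2 && sum(!is.na(v[!grp])) >= 2) {
        compare_continuous(v[grp], v[!grp])
      } else {
        list(statistic = NA_real_, p_value = NA_real_, test = "degenerate",
             mean = c(mean(v[grp], na.rm = TRUE), mean(v[!grp], na.rm = TRUE)),
             sd = c(stats::sd(v[grp], na.rm = TRUE),
                    stats::sd(v[!grp], na.rm = TRUE)))
      }
      return(tibble::tibble(
        characteristic = ch, type = "continuous", level = "mean ± SD",
        n_cardiac = sum(!is.na(v[grp])), pct_cardiac = NA_real_,
        mean_cardiac = cmp$mean[1], sd_cardiac = cmp$sd[1],
        n_other = sum(!is.na(v[!grp])), pct_other = NA_real_,
        mean_other = cmp$mean[2], sd_other = cmp$sd[2],
        missing_cardiac = miss1, missing_other = miss2,
        p_value = cmp$p_value, test = cmp$test
      ))
    }
    levs <- sort(unique(v[!is.na(v)]))
    n1 <- vapply(levs, function(l) sum(v == l & grp, na.rm = TRUE), integer(1))
    n2 <- vapply(levs, function(l) sum(v == l & !grp, na.rm = TRUE), integer(1))
    p <- NA_real_; test <- NA_character_
    if (length(levs) >= 2 && sum(n1) > 0 && sum(n2) > 0) {
      keep <- n1 + n2 > 0
      if (sum(keep) >= 2) {
        cmp <- compare_categorical(cbind(n1[keep], n2[keep]))
        p <- cmp$p_value; test <- cmp$test
      }
    }
    tibble::tibble(
      characteristic = ch, type = "categorical",
      level = if (length(levs)) as.character(levs) else "(all missing)",
      n_cardiac = if (length(levs)) unname(n1) else 0L,
      pct_cardiac = if (length(levs)) unname(tabulate_percent(n1)) else NA_real_,
      mean_cardiac = NA_real_, sd_cardiac = NA_real_,
      n_other = if (length(levs)) unname(n2) else 0L,
      pct_other = if (length(levs)) unname(tabulate_percent(n2)) else NA_real_,
      mean_other = NA_real_, sd_other = NA_real_,
      missing_cardiac = miss1, missing_other = miss2,
      p_value = p, test = test
    )
  })
  rows
}
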