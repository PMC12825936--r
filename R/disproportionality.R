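#' Build a 2x2 drug-event contingency table
#'
#' Counts each report exactly once into one of the four cells of the
#' disproportionality table: `a` exposed with the event, `b` exposed
#' without, `c` unexposed with, `d` neither.
#'
#' @param exposed,event Logical vectors of equal length, one element per
#'   report; `NA` is not allowed (predicates must be total).
#' @return A `contingency_2x2` list with elements `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(exposed, event) {
  stopifnot(is.logical(exposed), is.logical(event),
            length(exposed) == length(event))
  if (anyNA(exposed) || anyNA(event)) {
    stop("exposure/event predicates must be total (no NA)")
  }
  structure(
    list(
      a = sum(exposed & event),
      b = sum(exposed & !event),
      c = sum(!exposed & event),
      d = sum(!exposed & !event)
    ),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a/c) / (b/d) with the log-scale Woolf interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' Cells of zero leave the estimate undefined: by default the affected
#' tables yield `NA` with a warning carrying the table, rather than a
#' silent continuity correction; `correction = TRUE` applies the Haldane
#' 0.5 correction to all four cells of affected tables.
#'
#' @param a Either a `contingency_2x2` or the `a` cell; vectors accepted.
#' @param b,c,d Remaining cells when `a` is numeric.
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @param correction Apply Haldane 0.5 to zero-cell tables.
#' @return A tibble with columns `ror`, `ci_low`, `ci_high`.
#' @export
ror_ci <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96,
                   correction = FALSE) {
  if (inherits(a, "contingency_2x2")) {
    b <- a$b; c <- a$c; d <- a$d; a <- a$a
  }
  stopifnot(length(a) == length(b), length(a) == length(c),
            length(a) == length(d))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("cell counts must be >= 0")
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (any(zero, na.rm = TRUE)) {
    if (correction) {
      a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
      c[zero] <- c[zero] + 0.5; d[zero] <- d[zero] + 0.5
    } else {
      warning(sum(zero), " table(s) with a zero cell: ROR undefined ",
              "(use correction = TRUE for Haldane 0.5)")
    }
  }
  lr <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- tibble::tibble(
    ror = exp(lr),
    ci_low = exp(lr - z * se),
    ci_high = exp(lr + z * se)
  )
  if (!correction) out[which(zero), ] <- NA_real_
  out
}

# shared worker: per-PT signal table for a given exposure vector against
# the reports currently in `store` (the background)
signal_table <- function(store, term_map, exposed, min_events = 3,
                         stratum = "overall", soc = "cardiac disorders") {
  demo <- store$demo
  n_total <- nrow(demo)
  n_exposed <- sum(exposed)
  cardiac <- cardiac_pt_set(term_map, soc)
  rx <- store$reac
  rx$pt_norm <- normalize_term(rx$pt)
  rx <- rx[rx$pt_norm %in% cardiac, c("primaryid", "pt_norm")]
  rx <- rx[!duplicated(rx), ]
  rx$exposed <- exposed[match(rx$primaryid, demo$primaryid)]

  counts <- dplyr::summarise(
    dplyr::group_by(rx, .data$pt_norm),
    a = sum(.data$exposed),
    n_pt = dplyr::n(),
    .groups = "drop"
  )
  counts <- counts[counts$a >= 1, ]
  if (nrow(counts) == 0) {
    return(tibble::tibble(stratum = character(), pt = character(),
                          n_events = integer(), ror = double(),
                          ci_low = double(), ci_high = double(),
                          is_signal = logical()))
  }
  a <- counts$a
  b <- n_exposed - a
  cc <- counts$n_pt - a
  d <- n_total - n_exposed - cc
  est <- suppressWarnings(ror_ci(a, b, cc, d))
  out <- tibble::tibble(
    stratum = stratum,
    pt = counts$pt_norm,
    n_events = as.integer(a),
    ror = est$ror,
    ci_low = est$ci_low,
    ci_high = est$ci_high
  )
  out$is_signal <- out$n_events >= min_events &
    !is.na(out$ci_low) & out$ci_low > 1
  out[order(-out$n_events, -ifelse(is.na(out$ror), -Inf, out$ror), out$pt), ]
}

#' Screen cardiac preferred terms for disproportionality signals
#'
#' For every cardiac-disorders PT with at least one exposed report, builds
#' the 2x2 table of the PT against exposure to the target drugs (primary
#' suspect role) using all reports in the store as the background, and
#' applies the signal criterion: at least `min_events` exposed reports and
#' a 95% CI lower bound above one.
#'
#' @param store A deduplicated `faers_store` holding the full background
#'   database (not only exposed reports).
#' @param term_map PT to SOC map (see [read_term_map()]).
#' @param drug_names Target drug names defining exposure.
#' @param min_events Minimum exposed event count for a signal (3).
#' @param soc SOC whose PTs are screened.
#' @return A tibble with columns `stratum`, `pt`, `n_events`, `ror`,
#'   `ci_low`, `ci_high`, `is_signal`, sorted by `n_events` then `ror`
#'   descending (ties broken by PT).
#' @export
screen_signals <- function(store, term_map, drug_names, min_events = 3,
                           soc = "cardiac disorders") {
  exposed <- is_ps_exposed(store, drug_names)
  signal_table(store, term_map, exposed, min_events,
               stratum = "overall", soc = soc)
}

#' Subgroup disproportionality signals
#'
#' Repeats the PT-level screen within key subgroups. Sex, age-group and
#' cancer strata partition the database and each stratum is screened
#' against the background restricted to that stratum; drug strata instead
#' vary the exposure definition (one target drug at a time) against the
#' full background. Reports with a missing stratum value are excluded from
#' that stratification; empty strata are skipped.
#'
#' @inheritParams screen_signals
#' @param by Which stratifications to run, a subset of
#'   `c("sex", "age_group", "drug", "cancer")`.
#' @param age_cutoff Age separating the elderly stratum (years; elderly is
#'   strictly greater).
#' @return A tibble in the [screen_signals()] layout, `stratum` labelled
#'   `"<dimension>:<level>"`.
#' @export
stratified_signals <- function(store, term_map, drug_names,
                               by = c("sex", "age_group", "drug", "cancer"),
                               min_events = 3, age_cutoff = 65,
                               soc = "cardiac disorders") {
  by <- match.arg(by, several.ok = TRUE)
  demo <- store$demo
  flat <- flatten_reports(store)
  out <- list()

  run_partition <- function(values, dim) {
    for (lev in sort(unique(values[!is.na(values)]))) {
      ids <- demo$primaryid[!is.na(values) & values == lev]
      if (length(ids) == 0) next
      sub <- subset_store(store, ids)
      res <- signal_table(sub, term_map,
                          is_ps_exposed(sub, drug_names),
                          min_events,
                          stratum = paste0(dim, ":", lev), soc = soc)
      out[[length(out) + 1]] <<- res
    }
  }
  if ("sex" %in% by) {
    sx <- toupper(demo$sex)
    sx[!sx %in% c("F", "M")] <- NA
    run_partition(sx, "sex")
  }
  if ("age_group" %in% by) {
    ag <- ifelse(is.na(demo$age), NA,
                 ifelse(demo$age > age_cutoff, paste0(">", age_cutoff),
                        paste0("<=", age_cutoff)))
    run_partition(ag, "age_group")
  }
  if ("cancer" %in% by) {
    run_partition(flat$indication, "cancer")
  }
  if ("drug" %in% by) {
    for (dg in drug_names) {
      ex <- is_ps_exposed(store, dg)
      if (!any(ex)) next
      out[[length(out) + 1]] <- signal_table(
        store, term_map, ex, min_events,
        stratum = paste0("drug:", normalize_drug(dg)), soc = soc
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Compare signals for a drug class alone versus with a partner drug
#'
#' Builds paired signal tables for reports exposed to the target drugs as
#' primary suspect without the partner drug, and with the partner drug
#' co-reported in any role; both arms are screened against the full
#' database background. Used to study risk modification by concomitant
#' therapy (e.g. dexamethasone).
#'
#' @inheritParams screen_signals
#' @param partner Partner drug name matched in any role code.
#' @return A tibble in the [screen_signals()] layout with `stratum`
#'   `"alone"` or `"combination"`; empty (with a warning) when no report
#'   is co-exposed.
#' @export
combination_signals <- function(store, term_map, drug_names, partner,
                                min_events = 3, soc = "cardiac disorders") {
  base <- is_ps_exposed(store, drug_names)
  with_partner <- has_drug(store, partner)
  if (!any(base & with_partner)) {
    warning("no reports co-exposed to the target drugs and '", partner, "'")
    return(signal_table(store, term_map, rep(FALSE, nrow(store$demo)),
                        min_events, stratum = "combination", soc = soc))
  }
  dplyr::bind_rows(
    signal_table(store, term_map, base & !with_partner, min_events,
                 stratum = "alone", soc = soc),
    signal_table(store, term_map, base & with_partner, min_events,
                 stratum = "combination", soc = soc)
  )
}

#' Per-cancer composite cardiac ROR
#'
#' For each cancer indication, computes one composite signal where the
#' event is "any signal-positive cardiac PT" (by default the PTs flagged by
#' [screen_signals()]) and the exposure is a target drug as primary suspect
#' with that indication, against the full database background. Cancers with
#' fewer than `min_events` composite events are flagged non-evaluable.
#'
#' @inheritParams screen_signals
#' @param signal_pts Character vector of cardiac PTs defining the composite
#'   event; defaults to the signal-positive PTs of the overall screen.
#' @return A tibble with columns `cancer`, `n_events`, `ror`, `ci_low`,
#'   `ci_high`, `evaluable`, `is_signal`.
#' @export
cancer_composite_ror <- function(store, term_map, drug_names,
                                 signal_pts = NULL, min_events = 3,
                                 soc = "cardiac disorders") {
  if (is.null(signal_pts)) {
    sig <- screen_signals(store, term_map, drug_names,
                          min_events = min_events, soc = soc)
    signal_pts <- sig$pt[sig$is_signal]
  }
  flat <- flatten_reports(store)
  event <- has_pt(store, signal_pts)
  exposed_all <- is_ps_exposed(store, drug_names)
  cancers <- sort(unique(flat$indication[!is.na(flat$indication)]))
  res <- purrr::map_dfr(cancers, function(cn) {
    exp_c <- exposed_all & !is.na(flat$indication) & flat$indication == cn
    tab <- build_contingency(exp_c, event)
    est <- suppressWarnings(ror_ci(tab))
    tibble::tibble(
      cancer = cn, n_events = as.integer(tab$a),
      ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
      evaluable = tab$a >= min_events
    )
  })
  res$is_signal <- res$evaluable & !is.na(res$ci_low) & res$ci_low > 1
  res[order(-ifelse(is.na(res$ror), -Inf, res$ror)), ]
}
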