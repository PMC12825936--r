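#' FAERS-style report stores
#'
#' A `faers_store` keeps the six FAERS quarterly tables in their native
#' relational long format (one row per reaction, per drug mention, ...)
#' joined by `primaryid`. Before deduplication each DEMO row is one *case
#' version*; afterwards each row is one retained report.
#'
#' Expected columns (lowercase; extra columns are kept but ignored):
#' \describe{
#'   \item{demo}{`primaryid`, `caseid`, `fda_dt`, `event_dt`, `sex`,
#'     `age` (years), `wt` (kg), `occr_country`}
#'   \item{drug}{`primaryid`, `drugname`, `role_cod` (PS/SS/C/I)}
#'   \item{reac}{`primaryid`, `pt`}
#'   \item{outc}{`primaryid`, `outc_cod` (DE/LT/HO/DS/CA/RI/OT)}
#'   \item{ther}{`primaryid`, `start_dt`}
#'   \item{indi}{`primaryid`, `indi_pt`}
#' }
#'
#' @param tables Named list with elements `demo` (required) and optionally
#'   `drug`, `reac`, `outc`, `ther`, `indi`, each a data frame.
#' @return A `faers_store` object.
#' @export
as_faers_store <- function(tables) {
  stopifnot(is.list(tables), "demo" %in% names(tables))
  log <- list()

  demo <- tibble::as_tibble(tables$demo)
  need <- c("primaryid", "caseid")
  names(demo) <- tolower(names(demo))
  if (!all(need %in% names(demo))) {
    stop("DEMO table must contain columns: ", paste(need, collapse = ", "))
  }
  for (col in c("fda_dt", "event_dt", "sex", "occr_country")) {
    if (!col %in% names(demo)) demo[[col]] <- NA_character_
    demo[[col]] <- as.character(demo[[col]])
  }
  for (col in c("age", "wt")) {
    if (!col %in% names(demo)) demo[[col]] <- NA_real_
    demo[[col]] <- suppressWarnings(as.numeric(demo[[col]]))
  }
  demo$primaryid <- as.integer(demo$primaryid)
  demo$caseid <- as.integer(demo$caseid)

  bad_id <- is.na(demo$primaryid) | is.na(demo$caseid)
  if (any(bad_id)) {
    log$demo_bad_id <- sum(bad_id)
    demo <- demo[!bad_id, ]
  }
  dup <- duplicated(demo$primaryid)
  if (any(dup)) {
    log$demo_duplicate_primaryid <- sum(dup)
    warning(sum(dup), " DEMO row(s) with duplicated primaryid rejected")
    demo <- demo[!dup, ]
  }
  neg_age <- !is.na(demo$age) & demo$age < 0
  if (any(neg_age)) {
    log$demo_negative_age <- sum(neg_age)
    demo$age[neg_age] <- NA_real_
  }
  bad_wt <- !is.na(demo$wt) & demo$wt <= 0
  if (any(bad_wt)) {
    log$demo_nonpositive_weight <- sum(bad_wt)
    demo$wt[bad_wt] <- NA_real_
  }

  ids <- demo$primaryid
  clean_child <- function(tbl, value_col, name) {
    if (is.null(tbl)) {
      tbl <- tibble::tibble(primaryid = integer())
      tbl[[value_col]] <- character()
      return(tbl)
    }
    tbl <- tibble::as_tibble(tbl)
    names(tbl) <- tolower(names(tbl))
    if (!"primaryid" %in% names(tbl)) {
      stop(toupper(name), " table lacks a primaryid column")
    }
    tbl$primaryid <- suppressWarnings(as.integer(tbl$primaryid))
    if (!value_col %in% names(tbl)) tbl[[value_col]] <- NA_character_
    tbl[[value_col]] <- as.character(tbl[[value_col]])
    bad <- is.na(tbl$primaryid) | is.na(tbl[[value_col]]) |
      tbl[[value_col]] == ""
    orphan <- !is.na(tbl$primaryid) & !(tbl$primaryid %in% ids)
    drop <- bad | orphan
    if (any(drop)) {
      log[[paste0(name, "_dropped_rows")]] <<- sum(drop)
      tbl <- tbl[!drop, ]
    }
    if (nrow(tbl) == 0 && name %in% c("reac")) {
      warning("no usable rows in ", toupper(name),
              " table; reports will have empty reaction lists")
    }
    tbl
  }

  drug <- tables$drug
  if (!is.null(drug)) {
    drug <- tibble::as_tibble(drug)
    names(drug) <- tolower(names(drug))
    if (!"role_cod" %in% names(drug)) drug$role_cod <- NA_character_
    drug$role_cod <- toupper(as.character(drug$role_cod))
  }
  drug <- clean_child(drug, "drugname", "drug")
  if (!"role_cod" %in% names(drug)) drug$role_cod <- character(0)

  structure(
    list(
      demo = demo,
      drug = drug[, c("primaryid", "drugname", "role_cod")],
      reac = clean_child(tables$reac, "pt", "reac"),
      outc = clean_child(tables$outc, "outc_cod", "outc"),
      ther = clean_child(tables$ther, "start_dt", "ther"),
      indi = clean_child(tables$indi, "indi_pt", "indi")
    ),
    class = "faers_store",
    deduplicated = FALSE,
    load_log = log
  )
}

#' Read FAERS-style quarterly tables from disk
#'
#' Reads the `$`-delimited ASCII dialect used by FAERS quarterly extracts
#' (any single-character delimiter is accepted). Only the DEMO table is
#' required; malformed and orphan rows in the other tables are counted in
#' the load log rather than aborting the load.
#'
#' @param demo,drug,reac,outc,ther,indi File paths; all but `demo` may be
#'   `NULL`.
#' @param delim Field delimiter, `"$"` by default.
#' @return A `faers_store`; the load log is available via
#'   `attr(store, "load_log")`.
#' @export
read_faers_tables <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                              ther = NULL, indi = NULL, delim = "$") {
  if (is.null(demo) || !file.exists(demo)) {
    stop("DEMO file is required and must exist")
  }
  read1 <- function(path) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stop("file not found: ", path)
    out <- tryCatch(
      readr::read_delim(path, delim = delim,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE),
      error = function(e) stop("cannot parse '", path,
                               "' with delimiter '", delim, "': ",
                               conditionMessage(e))
    )
    out
  }
  as_faers_store(list(
    demo = read1(demo), drug = read1(drug), reac = read1(reac),
    outc = read1(outc), ther = read1(ther), indi = read1(indi)
  ))
}

#' @export
print.faers_store <- function(x, ...) {
  cat("<faers_store> ", nrow(x$demo),
      if (isTRUE(attr(x, "deduplicated"))) " reports" else " case versions",
      "\n", sep = "")
  cat("  drug rows: ", nrow(x$drug), ", reaction rows: ", nrow(x$reac),
      ", outcome rows: ", nrow(x$outc), "\n", sep = "")
  cat("  therapy rows: ", nrow(x$ther), ", indication rows: ",
      nrow(x$indi), "\n", sep = "")
  invisible(x)
}

# subset every table of a store to the given primaryids
subset_store <- function(store, primaryids) {
  for (tbl in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    store[[tbl]] <- store[[tbl]][store[[tbl]]$primaryid %in% primaryids, ]
  }
  store
}

# cross-field uniqueness signature: sex, age, country, event date,
# reactions, drugs, indications (sorted, normalized; NA -> "")
report_signatures <- function(store) {
  demo <- store$demo
  collapse_by <- function(tbl, col, norm) {
    v <- norm(tbl[[col]])
    out <- vapply(
      split(v, factor(tbl$primaryid, levels = demo$primaryid)),
      function(z) paste(sort(unique(z)), collapse = "|"),
      character(1)
    )
    out
  }
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  paste(
    blank(demo$sex), blank(demo$age), blank(demo$occr_country),
    blank(demo$event_dt),
    collapse_by(store$reac, "pt", normalize_term),
    collapse_by(store$drug, "drugname", normalize_drug),
    collapse_by(store$indi, "indi_pt", normalize_term),
    sep = "\x1f"
  )
}

#' Deduplicate FAERS case versions
#'
#' Applies the FDA-style deduplication rule: for identical `caseid`s the
#' version with the latest `fda_dt` is retained, and among versions sharing
#' the latest `fda_dt` the highest `primaryid` wins. A subsequent
#' cross-field uniqueness screen then removes reports (now one per caseid)
#' that are identical on sex, age, country, event date, reactions, drugs
#' and indications, again keeping the highest `primaryid`.
#'
#' Partial `fda_dt` values are padded to the first day of the period for
#' ordering only; missing dates sort first. The operation is idempotent.
#'
#' @param store A `faers_store`.
#' @return The deduplicated `faers_store`; counts of removed versions are
#'   in `attr(store, "dedup_log")`.
#' @export
faers_deduplicate <- function(store) {
  stopifnot(inherits(store, "faers_store"))
  demo <- store$demo
  n0 <- nrow(demo)
  if (n0 == 0) {
    attr(store, "deduplicated") <- TRUE
    attr(store, "dedup_log") <- list(n_versions = 0L, caseid_removed = 0L,
                                     crossfield_removed = 0L)
    return(store)
  }
  key <- pad_partial_date(demo$fda_dt)
  ord <- order(demo$caseid, key, demo$primaryid,
               decreasing = c(FALSE, TRUE, TRUE), method = "radix")
  demo_ord <- demo[ord, ]
  keep1 <- !duplicated(demo_ord$caseid)
  removed_case <- sum(!keep1)
  store <- subset_store(store, demo_ord$primaryid[keep1])

  sig <- report_signatures(store)
  demo <- store$demo
  ord2 <- order(sig, demo$primaryid, decreasing = c(FALSE, TRUE),
                method = "radix")
  keep2 <- !duplicated(sig[ord2])
  removed_cross <- sum(!keep2)
  store <- subset_store(store, demo$primaryid[ord2][keep2])
  store$demo <- store$demo[order(store$demo$primaryid), ]

  attr(store, "deduplicated") <- TRUE
  attr(store, "dedup_log") <- list(
    n_versions = n0,
    caseid_removed = removed_case,
    crossfield_removed = removed_cross
  )
  store
}

#' Restrict a store to reports with a target drug as primary suspect
#'
#' @param store A `faers_store`.
#' @param drug_names Character vector of target drug names; matching is
#'   exact after lowercasing and stripping whitespace/punctuation.
#' @return The filtered `faers_store`.
#' @export
filter_primary_suspect <- function(store, drug_names) {
  stopifnot(inherits(store, "faers_store"))
  if (length(drug_names) == 0) {
    stop("drug_names must contain at least one target drug")
  }
  keep <- store$demo$primaryid[is_ps_exposed(store, drug_names)]
  subset_store(store, keep)
}

#' Report-level exposure and event predicates
#'
#' `is_ps_exposed()` flags reports listing at least one target drug with
#' role code PS (primary suspect); `has_drug()` flags reports mentioning a
#' drug in any of the given role codes; `has_pt()` flags reports with at
#' least one of the given reaction preferred terms. All return a logical
#' vector aligned with the rows of `store$demo`.
#'
#' @param store A `faers_store`.
#' @param drug_names,drug,pts Target names/terms (normalized exact match).
#' @param roles Role codes to accept; `NULL` accepts any role.
#' @return Logical vector, one element per DEMO row.
#' @export
is_ps_exposed <- function(store, drug_names) {
  has_drug(store, drug_names, roles = "PS")
}

#' @rdname is_ps_exposed
#' @export
has_drug <- function(store, drug, roles = NULL) {
  dr <- store$drug
  hit <- normalize_drug(dr$drugname) %in% normalize_drug(drug)
  if (!is.null(roles)) hit <- hit & dr$role_cod %in% roles
  store$demo$primaryid %in% dr$primaryid[hit]
}

#' @rdname is_ps_exposed
#' @export
has_pt <- function(store, pts) {
  rx <- store$reac
  hit <- normalize_term(rx$pt) %in% normalize_term(pts)
  store$demo$primaryid %in% rx$primaryid[hit]
}

#' Read a PT to SOC term map
#'
#' MedDRA itself is licensed, so the pipeline works from a plain two-column
#' mapping (preferred term, system organ class). Every PT must map to one
#' primary SOC; duplicated PTs keep their first mapping.
#'
#' @param path Delimited text file with columns `pt` and `soc`.
#' @param delim Field delimiter, tab by default.
#' @return A tibble with columns `pt` and `soc`.
#' @export
read_term_map <- function(path, delim = "\t") {
  tm <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  names(tm) <- tolower(names(tm))
  stopifnot(all(c("pt", "soc") %in% names(tm)))
  tm <- tm[!duplicated(normalize_term(tm$pt)), c("pt", "soc")]
  tibble::as_tibble(tm)
}

# normalized PT set belonging to the cardiac-disorders SOC
cardiac_pt_set <- function(term_map, soc = "cardiac disorders") {
  normalize_term(term_map$pt)[normalize_term(term_map$soc) ==
                                normalize_term(soc)]
}

#' Flag reports with at least one cardiac-disorders reaction
#'
#' Adds `has_cardiac` and `n_cardiac_reactions` columns to the DEMO table.
#' A report is cardiac when at least one of its reaction PTs maps to the
#' system organ class "cardiac disorders" in `term_map`. PTs absent from
#' the map are retained in the reaction lists but never treated as cardiac;
#' their count is recorded in `attr(store, "unknown_pt_log")`.
#'
#' @param store A `faers_store`.
#' @param term_map Tibble with columns `pt` and `soc` (see
#'   [read_term_map()]).
#' @param soc SOC name identifying cardiac terms.
#' @return The annotated `faers_store` (same number of reports).
#' @export
tag_cardiac <- function(store, term_map, soc = "cardiac disorders") {
  stopifnot(inherits(store, "faers_store"))
  pts <- normalize_term(store$reac$pt)
  known <- pts %in% normalize_term(term_map$pt)
  cardiac <- pts %in% cardiac_pt_set(term_map, soc)
  card_ids <- unique(store$reac$primaryid[cardiac])
  store$demo$has_cardiac <- store$demo$primaryid %in% card_ids
  cnt <- table(factor(store$reac$primaryid[cardiac],
                      levels = store$demo$primaryid))
  store$demo$n_cardiac_reactions <- as.integer(cnt)
  attr(store, "unknown_pt_log") <- list(
    n_unknown_rows = sum(!known),
    unknown_pts = unique(store$reac$pt[!known])
  )
  store
}

# severity order used to pick one primary outcome per report
.outcome_severity <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Flatten a store to one row per report
#'
#' Produces the analysis table used by the descriptive, onset and
#' regression stages: demographics, dates, a single primary outcome (most
#' severe of the report's outcome codes, DE > LT > HO > DS > CA > RI > OT),
#' a fatality flag (any DE), the first recorded indication, the first
#' primary-suspect target drug and, when the store has been tagged, the
#' cardiac flag.
#'
#' @param store A `faers_store`.
#' @param target_drugs Optional target drug names used to fill `adc_drug`.
#' @return A tibble with one row per report.
#' @export
flatten_reports <- function(store, target_drugs = NULL) {
  demo <- store$demo
  lev <- demo$primaryid
  first_by <- function(tbl, col) {
    tbl <- tbl[order(tbl$primaryid), ]
    v <- vapply(split(tbl[[col]], factor(tbl$primaryid, levels = lev)),
                function(z) if (length(z)) z[[1]] else NA_character_,
                character(1))
    unname(v)
  }
  oc <- store$outc
  oc$rank <- match(toupper(oc$outc_cod), .outcome_severity)
  oc <- oc[order(oc$primaryid, oc$rank), ]
  primary_outcome <- unname(vapply(
    split(toupper(oc$outc_cod), factor(oc$primaryid, levels = lev)),
    function(z) if (length(z)) z[[1]] else NA_character_, character(1)
  ))
  fatal_ids <- unique(oc$primaryid[toupper(oc$outc_cod) == "DE"])

  out <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt,
    start_dt = first_by(store$ther, "start_dt"),
    sex = demo$sex,
    age_years = demo$age,
    weight_kg = demo$wt,
    country = demo$occr_country,
    outcome = unname(primary_outcome),
    fatal = ifelse(is.na(primary_outcome), NA,
                   demo$primaryid %in% fatal_ids),
    indication = normalize_term(first_by(store$indi, "indi_pt"))
  )
  if (!is.null(target_drugs)) {
    dr <- store$drug
    hit <- dr[dr$role_cod %in% "PS" &
                normalize_drug(dr$drugname) %in% normalize_drug(target_drugs), ]
    out$adc_drug <- normalize_drug(first_by(hit, "drugname"))
    out$adc_drug[which(out$adc_drug == "")] <- NA_character_
  }
  if ("has_cardiac" %in% names(demo)) out$has_cardiac <- demo$has_cardiac
  out
}
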