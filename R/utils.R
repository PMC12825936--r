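`%||%` <- function(x, y) if (is.null(x)) y else x

#' Pad a partial FAERS date for ordering
#'
#' FAERS date fields may carry a full day (`YYYYMMDD`), a month (`YYYYMM`),
#' a year (`YYYY`) or be empty. For ordering purposes partial dates are
#' padded to the first day of the period they cover and missing dates sort
#' before everything else.
#'
#' @param x Character vector of raw date strings.
#' @return Character vector of 8-digit keys suitable for lexicographic
#'   ordering.
#' @export
pad_partial_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("[^0-9]", "", x)
  n <- nchar(x)
  out <- rep("00000000", length(x))
  out[n == 4] <- paste0(x[n == 4], "0101")
  out[n == 6] <- paste0(x[n == 6], "01")
  out[n == 8] <- x[n == 8]
  out
}

#' Parse a strict 8-digit date
#'
#' Returns `NA` for anything that is not exactly eight digits or is not a
#' valid calendar date; partial dates are deliberately not coerced because
#' onset intervals require day-level precision.
#'
#' @param x Character vector of raw date strings.
#' @return A `Date` vector with `NA` where parsing failed.
#' @export
parse_full_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  d <- rep(as.Date(NA), length(x))
  ok <- grepl("^[0-9]{8}$", x)
  d[ok] <- as.Date(x[ok], format = "%Y%m%d")
  d
}

# lowercase + collapse internal whitespace; used for PT and SOC terms
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

# drug names additionally lose punctuation/whitespace so that e.g.
# "RC-48" and "rc48" match; exact match after normalization, no fuzzing
normalize_drug <- function(x) {
  gsub("[^a-z0-9]", "", tolower(as.character(x)))
}
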