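#' Convert a count matrix to transcripts per million
#'
#' Divides each gene's counts by its length in base pairs and rescales
#' each sample so the length-normalised rates sum to one million.
#' All-zero sample columns leave TPM undefined and are dropped with a
#' warning.
#'
#' @param counts Non-negative genes x samples matrix with rownames.
#' @param gene_lengths Positive lengths (bp), one per gene, in row order
#'   (or named by gene).
#' @return TPM matrix with the same dimnames (minus dropped columns).
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts),
            all(gene_lengths > 0), all(counts >= 0))
  rate <- counts / gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero sample(s) dropped (TPM undefined)")
    rate <- rate[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Rank-based per-sample scores of gene-set activity. Within each sample,
#' genes are ranked by expression (ascending, average ranks on ties) and
#' the gene list is walked in decreasing-expression order: in-set steps
#' are weighted by `rank^alpha` (normalised to sum to one over the set),
#' out-of-set steps are uniform `1/(N - |G|)`. The enrichment score is the
#' sum over all positions of the difference between the in-set and
#' out-of-set cumulative sums. With `normalize = TRUE` all scores are
#' divided by the range (max - min) of the whole score matrix.
#'
#' Scores depend on the data only through within-sample ranks, so they are
#' invariant under any strictly monotone per-sample transform of
#' expression.
#'
#' @param expr Expression matrix (e.g. TPM), genes x samples, with
#'   rownames.
#' @param gene_sets Named list of character vectors of gene names; sets
#'   with fewer than two genes present in the matrix are skipped with a
#'   warning.
#' @param alpha Rank-weighting exponent (0.25).
#' @param normalize Apply the matrix-wide range normalisation.
#' @return Sets x samples score matrix.
#' @export
ssgsea_scores <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  stopifnot(!is.null(genes), is.list(gene_sets), !is.null(names(gene_sets)))
  n <- nrow(expr)
  members <- lapply(gene_sets, function(g) which(genes %in% g))
  ok <- vapply(members, function(ix) length(ix) >= 2 && length(ix) < n,
               logical(1))
  if (any(!ok)) {
    warning("skipping gene set(s) with < 2 mapped genes (or covering ",
            "the whole matrix): ",
            paste(names(gene_sets)[!ok], collapse = ", "))
  }
  members <- members[ok]
  if (length(members) == 0) stop("no usable gene sets")

  es <- matrix(NA_real_, length(members), ncol(expr),
               dimnames = list(names(members), colnames(expr)))
  ind <- matrix(FALSE, n, length(members))
  for (s in seq_along(members)) ind[members[[s]], s] <- TRUE

  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x)
    ord <- order(x, decreasing = TRUE)
    ra <- r^alpha
    for (s in seq_along(members)) {
      in_set <- ind[, s]
      w <- ra * in_set
      step_in <- w[ord] / sum(w)
      step_out <- (!in_set)[ord] / (n - sum(in_set))
      es[s, j] <- sum(cumsum(step_in) - cumsum(step_out))
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

#' Mean pathway activity per cancer type
#'
#' The arithmetic mean enrichment score of a pathway over the samples of a
#' cancer type represents the activation level of that pathway in that
#' cancer.
#'
#' @param scores Sets x samples matrix from [ssgsea_scores()].
#' @param sample_cancers Cancer label per sample (column order or named by
#'   sample).
#' @return Cancers x pathways matrix of mean scores.
#' @export
per_cancer_activity <- function(scores, sample_cancers) {
  scores <- as.matrix(scores)
  if (!is.null(names(sample_cancers)) && !is.null(colnames(scores))) {
    sample_cancers <- sample_cancers[colnames(scores)]
  }
  stopifnot(length(sample_cancers) == ncol(scores))
  g <- factor(sample_cancers)
  m <- do.call(rbind, lapply(levels(g), function(l) {
    rowMeans(scores[, g == l, drop = FALSE])
  }))
  dimnames(m) <- list(levels(g), rownames(scores))
  m
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho by Pearson correlation of average ranks and the two-sided
#' p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. A constant input leaves rho undefined (NA with a warning).
#'
#' @param x,y Numeric vectors of equal length (pairwise complete).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Correlate per-cancer cardiac RORs with pathway activity
#'
#' Matches cancers between the composite-ROR table and the per-cancer
#' activity matrix and computes, for each pathway, the Spearman rank
#' correlation between the cancers' composite cardiac RORs and their mean
#' enrichment scores. Reported unadjusted, as is conventional for this
#' screen; `adjust = TRUE` adds a Benjamini-Hochberg column.
#'
#' @param rors Either a named numeric vector of composite RORs (names are
#'   cancer labels) or a tibble with columns `cancer` and `ror` (e.g. from
#'   [cancer_composite_ror()]; non-evaluable rows should be dropped first).
#' @param activity Cancers x pathways matrix from [per_cancer_activity()].
#' @param adjust Add a BH-adjusted p-value column.
#' @return A tibble (`pathway`, `rho`, `p_value`, `n`) sorted by absolute
#'   rho, descending.
#' @export
correlate_ror_pathways <- function(rors, activity, adjust = FALSE) {
  if (is.data.frame(rors)) {
    stopifnot(all(c("cancer", "ror") %in% names(rors)))
    rors <- stats::setNames(rors$ror, rors$cancer)
  }
  activity <- as.matrix(activity)
  common <- intersect(names(rors)[!is.na(rors)], rownames(activity))
  if (length(common) < 4) {
    stop("need at least 4 cancers with both a composite ROR and activity")
  }
  r <- rors[common]
  res <- purrr::map_dfr(colnames(activity), function(pw) {
    ct <- withCallingHandlers(
      spearman_cor_test(r, activity[common, pw]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(pathway = pw, rho = ct$rho, p_value = ct$p_value,
                   n = ct$n)
  })
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res[order(-abs(ifelse(is.na(res$rho), -Inf, res$rho))), ]
}

#' Read and write GMT gene-set files
#'
#' `read_gmt()` parses the standard tab-separated GMT format (set name,
#' description, member genes) via the fgsea parser; `write_gmt()` emits
#' it.
#'
#' @param path File path.
#' @param gene_sets Named list of character vectors.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT files requires the fgsea package")
  }
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
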