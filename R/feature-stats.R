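# Chi-squared substructure enrichment: ranks fingerprint features by
# association of their class-wise count sums with epitope status, and
# computes the interpretability statistics reported per feature: Bonferroni-
# corrected p, epitope coverage, fold-enrichment and mean count difference.

# Class-wise count-sum chi-squared test, one feature per column.
# Observed: the feature's count summed within each class. Expected: the
# feature's total count split by class share of molecules. 1 df (two
# classes). Zero-total features carry stat 0 / p 1.
#' @noRd
.chi2_stats <- function(counts, labels) {
  labels <- as.logical(labels)
  n <- length(labels)
  np <- sum(labels)
  o_pos <- colSums(counts[labels, , drop = FALSE])
  o_neg <- colSums(counts[!labels, , drop = FALSE])
  total <- o_pos + o_neg
  e_pos <- total * np / n
  e_neg <- total * (n - np) / n
  stat <- ifelse(total == 0, 0,
                 (o_pos - e_pos)^2 / e_pos + (o_neg - e_neg)^2 / e_neg)
  p <- ifelse(total == 0, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(stat = unname(stat), p = unname(p))
}

#' Chi-squared association test per fingerprint feature
#'
#' For each feature the observed quantity is its count summed within each
#' class; the expected split follows the class shares of molecules. The test
#' has one degree of freedom (two classes). A feature with zero total count
#' carries no evidence and reports p = 1 (with a message).
#'
#' @param fm A feature matrix.
#' @param labels Logical labels (both classes present).
#' @return Numeric vector of raw p-values, one per feature column, with the
#'   chi-squared statistics attached as attribute `"statistic"`.
#' @export
chi2_feature_test <- function(fm, labels) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    npek_stop("chi-squared test requires both classes", "npek_metric_error")
  res <- .chi2_stats(fm$counts, labels)
  if (any(res$p == 1 & res$stat == 0 & colSums(fm$counts) == 0))
    message("feature(s) with zero total count: p set to 1")
  structure(res$p, statistic = res$stat)
}

#' Bonferroni correction
#'
#' @param raw_p Numeric vector of raw p-values.
#' @param m Number of tests (defaults to `length(raw_p)`; must be at least
#'   that).
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(raw_p, m = length(raw_p)) {
  if (m < length(raw_p))
    npek_stop("m must be at least the number of p-values", "npek_param_error")
  stats::p.adjust(raw_p, method = "bonferroni", n = m)
}

#' Per-feature enrichment statistics
#'
#' For every feature: epitope coverage (fraction of positives containing the
#' feature at least once), fold-enrichment (epitope coverage divided by
#' background coverage; `NA` when no background molecule contains the
#' feature) and mean count difference (mean count among feature-containing
#' positives minus mean count among feature-containing background molecules;
#' `NA` when no background molecule contains the feature; 0 stands in for the
#' positive-side mean when no positive contains it). Rows are sorted by
#' corrected p ascending, ties toward the lower feature id. `NA` renders as
#' `"-"` in text reports.
#'
#' @param fm A feature matrix.
#' @param labels Logical labels (TRUE = epitope).
#' @return A data.frame of class `"npek_feature_stats"` with columns
#'   `feature_id`, `raw_p`, `corrected_p`, `epitope_coverage`,
#'   `fold_enrichment`, `mean_count_difference`.
#' @export
feature_statistics <- function(fm, labels) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  labels <- as.logical(labels)
  raw_p <- as.numeric(chi2_feature_test(fm, labels))
  corrected_p <- bonferroni(raw_p, m = ncol(fm$counts))
  pos <- fm$counts[labels, , drop = FALSE]
  neg <- fm$counts[!labels, , drop = FALSE]
  cov_pos <- colMeans(pos >= 1L)
  cov_neg <- colMeans(neg >= 1L)
  fold <- ifelse(cov_neg == 0, NA_real_, cov_pos / cov_neg)
  mean_if_present <- function(mat, j) {
    v <- mat[, j][mat[, j] >= 1L]
    if (length(v) == 0L) 0 else mean(v)
  }
  mcd <- vapply(seq_len(ncol(fm$counts)), function(j) {
    if (cov_neg[j] == 0) return(NA_real_)
    mean_if_present(pos, j) - mean_if_present(neg, j)
  }, 0)
  out <- data.frame(
    feature_id = fm$feature_ids,
    raw_p = raw_p,
    corrected_p = corrected_p,
    epitope_coverage = unname(cov_pos),
    fold_enrichment = unname(fold),
    mean_count_difference = mcd
  )
  out <- out[order(out$corrected_p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("npek_feature_stats", "data.frame")
  out
}

#' @export
print.npek_feature_stats <- function(x, digits = 3, max_rows = 20, ...) {
  df <- utils::head(as.data.frame(x), max_rows)
  df$feature_id <- sprintf("%.0f", df$feature_id)
  df$fold_enrichment <- ifelse(is.na(df$fold_enrichment), "-",
                               format(round(df$fold_enrichment, digits)))
  df$mean_count_difference <- ifelse(is.na(df$mean_count_difference), "-",
                                     format(round(df$mean_count_difference, digits)))
  print.data.frame(df)
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more features\n")
  invisible(x)
}

#' Report the most significant features with their substructures
#'
#' Takes the `max_features` most significant rows and joins each with the
#' substructure fragment resolved on an example molecule: the containing
#' positive with the lowest `mol_id`, falling back to any containing
#' molecule for background-enriched features.
#'
#' @param stats A [feature_statistics()] table (sorted by corrected p).
#' @param max_features Maximum number of rows (default 8).
#' @param fm The feature matrix the statistics were computed on.
#' @param molecules The molecule set behind `fm` (provides SMILES).
#' @param labels Logical labels aligned with `fm` rows.
#' @return `stats` rows joined with `example_mol_id` and `fragment_smiles`.
#' @export
top_features_report <- function(stats, max_features = 8L, fm, molecules,
                                labels) {
  stopifnot(inherits(stats, "npek_feature_stats"),
            inherits(fm, "npek_feature_matrix"))
  labels <- as.logical(labels)
  top <- utils::head(as.data.frame(stats), max_features)
  ex_id <- character(nrow(top))
  frag <- character(nrow(top))
  for (i in seq_len(nrow(top))) {
    j <- match(top$feature_id[i], fm$feature_ids)
    containing <- fm$counts[, j] >= 1L
    cand <- fm$mol_ids[containing & labels]
    if (length(cand) == 0L) cand <- fm$mol_ids[containing]
    ex_id[i] <- sort(cand)[1]
    m <- molecules[molecules$mol_id == ex_id[i], , drop = FALSE]
    frag[i] <- feature_substructure(m, top$feature_id[i],
                                    fm$params)$fragment_smiles
  }
  top$example_mol_id <- ex_id
  top$fragment_smiles <- frag
  class(top) <- c("npek_feature_report", "data.frame")
  top
}
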