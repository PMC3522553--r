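#' Shannon entropy of a descriptor feature
#'
#' Inter-cell-line weight of a feature: the Shannon entropy (base 2, bits) of
#' the empirical distribution of its discretized values over compounds.
#' Integer-valued features (counts, as in drug-like indices) use their
#' distinct values as bins; continuous features use `n_bins` equal-width bins.
#' A feature constant across all compounds carries no information and has
#' entropy exactly 0.
#'
#' @param column numeric vector of one feature's values over the m compounds.
#' @param n_bins number of equal-width bins for non-integer features.
#' @param normalize divide by `log2(#bins)` so the result lies in \[0, 1\].
#' @return Nonnegative scalar (bits); bounded by `log2(m)`.
#' @examples
#' feature_entropy(c(0, 0, 1, 2)) # 1.5 bits
#' @export
feature_entropy <- function(column, n_bins = 10, normalize = FALSE) {
  if (!length(column)) stopf("empty feature column")
  if (any(!is.finite(column))) stopf("feature values must be finite")
  if (length(unique(column)) == 1L) return(0)
  integerish <- all(abs(column - round(column)) < 1e-8)
  counts <- if (integerish) {
    table(round(column))
  } else {
    table(cut(column, breaks = n_bins, include.lowest = TRUE))
  }
  p <- counts[counts > 0] / sum(counts)
  H <- -sum(p * log2(p))
  if (normalize && length(p) > 1L) H <- H / log2(length(counts))
  as.numeric(H)
}

#' Dependency of a quantitative feature on one cell line's activity
#'
#' The intra-cell-line weight for quantitative features: the absolute Pearson
#' correlation between the feature and the observed activities, restricted to
#' compounds observed in that cell line. Zero if either side has zero
#' variance.
#'
#' @param feature numeric feature values for the observed compounds.
#' @param activity observed activity values, same length (>= 2).
#' @return Scalar in \[0, 1\].
#' @export
dependency_quantitative <- function(feature, activity) {
  if (length(feature) != length(activity))
    stopf("feature and activity lengths differ")
  if (length(feature) < 2L) stopf("need at least 2 paired observations")
  if (stats::sd(feature) == 0 || stats::sd(activity) == 0) return(0)
  abs(stats::cor(feature, activity))
}

#' Dependency of a qualitative feature on one cell line's activity
#'
#' The intra-cell-line weight for categorical features: Pearson's contingency
#' coefficient `C = sqrt(chi2 / (chi2 + N))` on the table of feature
#' categories against activity quantile bins (quartiles by default). A
#' degenerate table (a single category or a single non-empty activity bin)
#' returns 0.
#'
#' @param feature categorical (or category-coded) feature values for the
#'   observed compounds.
#' @param activity observed activity values, same length.
#' @param n_bins number of activity quantile bins (default 4 = quartiles).
#' @return Scalar in \[0, 1).
#' @export
dependency_qualitative <- function(feature, activity, n_bins = 4) {
  if (length(feature) != length(activity))
    stopf("feature and activity lengths differ")
  if (length(feature) < 2L) stopf("need at least 2 paired observations")
  breaks <- unique(stats::quantile(activity, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2L) return(0) # constant activity
  bins <- cut(activity, breaks = breaks, include.lowest = TRUE)
  tab <- table(factor(feature), bins)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (chi2 + sum(tab))))
}

#' Collaborative feature-weighting report
#'
#' The three-step weighting scheme for descriptor features across multiple
#' cell lines:
#' \enumerate{
#'   \item inter-cell-line weight: [feature_entropy()] of each feature,
#'     independent of any cell line;
#'   \item intra-cell-line weight: the dependency of each feature on each cell
#'     line's observed activities — absolute Pearson correlation for
#'     quantitative features, contingency coefficient for qualitative ones;
#'   \item final weight: the entry-wise product, `final[i, j] =
#'     entropy[j] * dependency[i, j]`.
#' }
#' A feature constant across compounds (e.g. a count absent from every
#' compound) gets entropy 0 and hence final weight exactly 0 in every cell
#' line.
#'
#' @param x an [activity_table()].
#' @param y an aligned [descriptor_table()]; each feature's `kind` selects the
#'   dependency measure.
#' @param n_bins bins for continuous-feature entropy (see [feature_entropy()]).
#' @param normalize normalize entropies by `log2(#bins)`.
#' @return Object of class `feature_weight_report`: `entropy` (length-r named
#'   vector), `dependency` and `final` (n x r matrices, rows = cell lines).
#' @export
weight_matrix <- function(x, y, n_bins = 10, normalize = FALSE) {
  pair <- align_tables(x, y)
  x <- pair$activity; y <- pair$descriptors
  n <- ncol(x$values); r <- ncol(y$values)
  H <- vapply(seq_len(r),
              function(j) feature_entropy(y$values[, j], n_bins, normalize),
              numeric(1))
  names(H) <- y$feature_names
  dep <- matrix(0, n, r, dimnames = list(x$cellline_ids, y$feature_names))
  for (i in seq_len(n)) {
    obs <- x$mask[, i] == 1
    act <- x$values[obs, i]
    for (j in seq_len(r)) {
      f <- y$values[obs, j]
      dep[i, j] <- if (y$kinds[j] == "quantitative")
        dependency_quantitative(f, act)
      else dependency_qualitative(f, act)
    }
  }
  final <- sweep(dep, 2, H, "*")
  structure(list(entropy = H, dependency = dep, final = final,
                 feature_names = y$feature_names,
                 cellline_ids = x$cellline_ids),
            class = "feature_weight_report")
}

#' @export
print.feature_weight_report <- function(x, ...) {
  cat(sprintf("feature_weight_report: %d features x %d cell lines\n",
              length(x$entropy), nrow(x$final)))
  top <- order(colMeans(x$final), decreasing = TRUE)[seq_len(min(5, length(x$entropy)))]
  cat("top features by mean final weight:",
      paste(x$feature_names[top], collapse = ", "), "\n")
  invisible(x)
}

#' Write a feature-weight report to CSV
#'
#' One row per feature: entropy, then one dependency column and one final
#' weight column per cell line.
#'
#' @param report a `feature_weight_report`.
#' @param path output CSV path.
#' @export
write_weight_csv <- function(report, path) {
  df <- data.frame(feature = report$feature_names, entropy = report$entropy,
                   check.names = FALSE)
  for (cl in report$cellline_ids)
    df[[paste0("dependency.", cl)]] <- report$dependency[cl, ]
  for (cl in report$cellline_ids)
    df[[paste0("final.", cl)]] <- report$final[cl, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
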