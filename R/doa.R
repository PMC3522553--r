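#' Leverage of query compounds relative to a training design
#'
#' The hat-matrix diagonal generalized to arbitrary query rows:
#' `h_i = x_i' (X'X)^{-1} x_i`, with `X` the n_train x k training descriptor
#' matrix and `x_i` a query descriptor row. Leverage measures a compound's
#' distance from the training descriptor space; predictions at high leverage
#' are extrapolations. When the Gram matrix is rank-deficient the
#' Moore-Penrose pseudoinverse is used and a warning is raised.
#'
#' @param train_descriptors n_train x k numeric matrix (or
#'   [descriptor_table()]).
#' @param query_descriptors q x k matrix of query rows; defaults to the
#'   training matrix itself (then the leverages sum to k in the full-rank
#'   case).
#' @param center subtract training column means from both matrices first.
#' @return Numeric vector of q nonnegative leverages.
#' @export
leverages <- function(train_descriptors, query_descriptors = train_descriptors,
                      center = FALSE) {
  X <- if (inherits(train_descriptors, "descriptor_table"))
    train_descriptors$values else as.matrix(train_descriptors)
  Q <- if (inherits(query_descriptors, "descriptor_table"))
    query_descriptors$values else as.matrix(query_descriptors)
  if (nrow(X) < 1L) stopf("need at least one training row")
  if (ncol(Q) != ncol(X))
    stopf("descriptor count mismatch: training k=%d, query k=%d", ncol(X), ncol(Q))
  if (center) {
    mu <- colMeans(X)
    X <- sweep(X, 2, mu, "-")
    Q <- sweep(Q, 2, mu, "-")
  }
  G <- crossprod(X)
  full_rank <- qr(G)$rank == ncol(X)
  Gi <- if (full_rank) solve(G) else {
    warnf("singular training Gram matrix (rank %d < k=%d); using pseudoinverse",
          qr(G)$rank, ncol(X))
    MASS::ginv(G)
  }
  h <- rowSums((Q %*% Gi) * Q)
  pmax(h, 0)
}

#' Warning leverage threshold
#'
#' The conventional cutoff `h* = 3k / n`: a query with leverage beyond it lies
#' outside the model's descriptor-space domain of applicability.
#'
#' @param k number of descriptors.
#' @param n_train number of training compounds.
#' @return Positive scalar `3 * k / n_train`.
#' @export
warning_leverage <- function(k, n_train) {
  if (k < 1 || n_train < 1) stopf("k and n_train must be positive")
  3 * k / n_train
}

#' Williams-plot table (domain-of-applicability report)
#'
#' Pairs each query compound's leverage with its standardized prediction
#' residual (residual divided by the root-mean-square of all residuals; zero
#' when every residual is zero). Compounds are flagged as structural (X)
#' outliers when `h > h* = 3k/n_train` and as response (Y) outliers when the
#' standardized residual exceeds 3 sigma in magnitude. Plotting standardized
#' residuals against leverage gives the Williams plot.
#'
#' @param train_descriptors training design (rows = training compounds).
#' @param query_descriptors q x k matrix of evaluated compounds.
#' @param residuals length-q vector of prediction residuals (observed minus
#'   predicted) for the queries.
#' @param compound_ids optional identifiers for the queries.
#' @param center pass-through to [leverages()].
#' @return Object of class `doa_report`: `table` (data frame compound_id,
#'   leverage, std_residual, x_outlier, y_outlier) and scalars `k`, `n_train`,
#'   `warning_leverage`, `sigma` (the residual RMS).
#' @export
williams_table <- function(train_descriptors, query_descriptors, residuals,
                           compound_ids = NULL, center = FALSE) {
  X <- if (inherits(train_descriptors, "descriptor_table"))
    train_descriptors$values else as.matrix(train_descriptors)
  Q <- if (inherits(query_descriptors, "descriptor_table"))
    query_descriptors$values else as.matrix(query_descriptors)
  if (length(residuals) != nrow(Q))
    stopf("residuals length %d does not match %d query rows",
          length(residuals), nrow(Q))
  h <- leverages(X, Q, center = center)
  k <- ncol(X); n_train <- nrow(X)
  hstar <- warning_leverage(k, n_train)
  sigma <- sqrt(mean(residuals^2))
  std <- if (sigma > 0) residuals / sigma else rep(0, length(residuals))
  ids <- compound_ids %||% rownames(Q) %||% paste0("query_", seq_len(nrow(Q)))
  tab <- data.frame(compound_id = ids, leverage = h, std_residual = std,
                    x_outlier = h > hstar, y_outlier = abs(std) > 3,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, k = k, n_train = n_train,
                 warning_leverage = hstar, sigma = sigma),
            class = "doa_report")
}

#' @export
print.doa_report <- function(x, ...) {
  cat(sprintf("doa_report: %d queries, k=%d, n_train=%d, h*=%.4f; %d X outliers, %d Y outliers\n",
              nrow(x$table), x$k, x$n_train, x$warning_leverage,
              sum(x$table$x_outlier), sum(x$table$y_outlier)))
  invisible(x)
}

#' Write a DOA report
#'
#' CSV with one row per query compound plus a JSON scalar block (k, n_train,
#' warning leverage, sigma).
#'
#' @param report a `doa_report`.
#' @param path output CSV path.
#' @param json_path optional path for the scalar block.
#' @export
write_doa_report <- function(report, path, json_path = NULL) {
  utils::write.csv(report$table, path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(k = report$k, n_train = report$n_train,
                              warning_leverage = report$warning_leverage,
                              sigma = report$sigma),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
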