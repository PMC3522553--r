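#' Root mean squared error
#'
#' `sqrt(mean((observed - predicted)^2))`.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0L) stopf("empty vectors")
  if (length(observed) != length(predicted))
    stopf("length mismatch: %d vs %d", length(observed), length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Squared correlation coefficient (coefficient of determination)
#'
#' `1 - SS_err / SS_tot`, with `SS_tot` about the observed mean. Can be
#' negative when the predictions do worse than the observed mean; equals 1
#' exactly when predictions are perfect.
#'
#' @param observed,predicted equal-length numeric vectors, length >= 2;
#'   `observed` must not be constant (otherwise the metric is undefined).
#' @return Scalar <= 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stopf("length mismatch: %d vs %d", length(observed), length(predicted))
  if (length(observed) < 2L) stopf("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stopf("R-squared undefined: observed values are constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Ridge regression with unpenalized intercept
#'
#' Closed-form penalized least squares: descriptors are centered (and by
#' default scaled to unit variance using training statistics), the response is
#' centered, and the coefficient vector solves
#' `(X'X + alpha I) w = X'y` on the centered data; the intercept is the
#' training response mean (unpenalized).
#'
#' @param x numeric training matrix (rows = compounds) or
#'   [descriptor_table()].
#' @param y numeric response vector (activities of one cell line).
#' @param alpha nonnegative ridge penalty; `alpha = 0` requires a full-rank
#'   design.
#' @param standardize scale columns to unit training variance (zero-variance
#'   columns are left unscaled).
#' @return Object of class `ridge_fit` with `coef`, `intercept`, and the
#'   centering/scaling statistics; use `predict()` on new rows.
#' @export
fit_ridge <- function(x, y, alpha = 1, standardize = TRUE) {
  X <- if (inherits(x, "descriptor_table")) x$values else as.matrix(x)
  if (nrow(X) < 2L) stopf("need at least 2 training rows")
  if (length(y) != nrow(X)) stopf("response length does not match design rows")
  if (alpha < 0) stopf("alpha must be nonnegative")
  k <- ncol(X)
  center <- colMeans(X)
  scale_ <- if (standardize) apply(X, 2, stats::sd) else rep(1, k)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale_, "/")
  ym <- mean(y)
  A <- crossprod(Xs) + alpha * diag(k)
  w <- tryCatch(solve(A, crossprod(Xs, y - ym)),
                error = function(e)
                  stopf("singular normal equations (alpha = %g); use alpha > 0", alpha))
  structure(list(coef = drop(w), intercept = ym, center = center,
                 scale = scale_, alpha = alpha,
                 feature_names = colnames(X)),
            class = "ridge_fit")
}

#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "descriptor_table")) newdata$values else as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center, "-"), 2, object$scale, "/")
  drop(Xs %*% object$coef) + object$intercept
}

# single-cell-line baselines; descriptors pre-scaled with training statistics
fit_baseline <- function(method, Y_tr, a_tr, Y_te, ridge_alpha, svr_args) {
  ctr <- colMeans(Y_tr)
  scl <- apply(Y_tr, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z_tr <- sweep(sweep(Y_tr, 2, ctr, "-"), 2, scl, "/")
  Z_te <- sweep(sweep(Y_te, 2, ctr, "-"), 2, scl, "/")
  if (method == "ridge") {
    fit <- fit_ridge(Z_tr, a_tr, alpha = ridge_alpha, standardize = FALSE)
    predict(fit, Z_te)
  } else { # svr: radial-kernel support vector regression
    fit <- do.call(e1071::svm,
                   c(list(x = Z_tr, y = a_tr, scale = FALSE), svr_args))
    as.numeric(stats::predict(fit, Z_te))
  }
}

#' Compare CMF against single-cell-line baselines
#'
#' For each cell line and each repeat: the compound set is split into train
#' and test; ridge and SVR are trained on the training compounds' descriptors
#' and that cell line's observed training activities; CMF masks the test cells
#' of that column only (keeping the rest of the column and all other columns)
#' and is fitted once per column per repeat. All methods are scored on exactly
#' the same observed test cells with [rmse()] and [r_squared()].
#'
#' @param x an [activity_table()].
#' @param y a [descriptor_table()] over the same compounds.
#' @param protocol `"random"` (seeded 2/3-1/3 splits, `repeats` times) or
#'   `"diverse_subset"` (single deterministic diversity-ranked split).
#' @param repeats number of random repeats (default 10); forced to 1 for the
#'   diverse protocol.
#' @param seed base integer seed; repeat k uses seed `seed + k - 1`.
#' @param methods subset of `c("cmf", "ridge", "svr")`.
#' @param control [cmf_control()] for the CMF fits.
#' @param test_fraction held-out fraction (default 1/3).
#' @param ridge_alpha ridge penalty (default 1).
#' @param svr_args list of extra arguments passed to [e1071::svm()].
#' @return Object of class `comparison_report`: `metrics` (data frame
#'   cell_line, method, repeat, rmse, r_squared), `errors` (per-test-compound
#'   squared errors), `protocol`.
#' @export
run_comparison <- function(x, y, protocol = c("random", "diverse_subset"),
                           repeats = 10, seed = 1,
                           methods = c("cmf", "ridge", "svr"),
                           control = cmf_control(), test_fraction = 1 / 3,
                           ridge_alpha = 1, svr_args = list()) {
  protocol <- match.arg(protocol)
  methods <- match.arg(methods, several.ok = TRUE)
  pair <- align_tables(x, y)
  x <- pair$activity; y <- pair$descriptors
  m <- nrow(x$values); n <- ncol(x$values)
  Y <- y$values

  plans <- if (protocol == "random") {
    lapply(seq_len(repeats), function(k) random_split(m, test_fraction, seed + k - 1))
  } else {
    repeats <- 1L
    list(diverse_split(y, test_fraction))
  }

  metrics <- list(); errors <- list()
  for (rep_i in seq_along(plans)) {
    plan <- plans[[rep_i]]
    for (j in seq_len(n)) {
      obs_tr <- plan$train[x$mask[plan$train, j] == 1]
      obs_te <- plan$test[x$mask[plan$test, j] == 1]
      if (length(obs_tr) < 2L || length(obs_te) < 2L) {
        warnf("cell line '%s' skipped in repeat %d: too few observed values",
              x$cellline_ids[j], rep_i)
        next
      }
      truth <- x$values[obs_te, j]
      preds <- list()
      if ("cmf" %in% methods) {
        x_masked <- mask_cells(x, plan$test, j)
        fit <- fit_cmf(x_masked, y, control = control,
                       seed = seed + 1000L * rep_i + j)
        preds$cmf <- predict(fit)[obs_te, j]
      }
      for (mth in intersect(methods, c("ridge", "svr"))) {
        preds[[mth]] <- fit_baseline(mth,
                                     Y[obs_tr, , drop = FALSE], x$values[obs_tr, j],
                                     Y[obs_te, , drop = FALSE],
                                     ridge_alpha, svr_args)
      }
      for (mth in names(preds)) {
        metrics[[length(metrics) + 1L]] <- data.frame(
          cell_line = x$cellline_ids[j], method = mth, repeat_ = rep_i,
          rmse = rmse(truth, preds[[mth]]),
          r_squared = tryCatch(r_squared(truth, preds[[mth]]),
                               error = function(e) NA_real_),
          stringsAsFactors = FALSE)
        errors[[length(errors) + 1L]] <- data.frame(
          cell_line = x$cellline_ids[j], method = mth, repeat_ = rep_i,
          compound_id = x$compound_ids[obs_te],
          squared_error = (truth - preds[[mth]])^2,
          stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  errors <- do.call(rbind, errors)
  rownames(errors) <- NULL
  structure(list(metrics = metrics, errors = errors, protocol = protocol,
                 repeats = repeats, seed = seed, methods = methods),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (%s, %d repeat(s))\n", x$protocol, x$repeats))
  agg <- stats::aggregate(cbind(rmse, r_squared) ~ cell_line + method,
                          data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Paired significance of CMF against each baseline
#'
#' Two-sided paired Wilcoxon signed-rank test on per-repeat metric values,
#' CMF vs each baseline within each cell line. Informative only with several
#' repeats (the random protocol); reported, never used as a gate.
#'
#' @param report a `comparison_report` from [run_comparison()].
#' @param metric `"rmse"` or `"r_squared"`.
#' @return Data frame: cell_line, baseline, p_value.
#' @export
method_significance <- function(report, metric = c("rmse", "r_squared")) {
  metric <- match.arg(metric)
  df <- report$metrics
  baselines <- setdiff(unique(df$method), "cmf")
  out <- list()
  for (cl in unique(df$cell_line)) {
    a <- df[df$cell_line == cl & df$method == "cmf", ]
    a <- a[order(a$repeat_), metric]
    for (b in baselines) {
      bb <- df[df$cell_line == cl & df$method == b, ]
      bb <- bb[order(bb$repeat_), metric]
      p <- if (length(a) == length(bb) && length(a) >= 2)
        suppressWarnings(stats::wilcox.test(a, bb, paired = TRUE)$p.value)
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(cell_line = cl, baseline = b,
                                            p_value = p)
    }
  }
  do.call(rbind, out)
}

#' Write a comparison report to tidy CSV
#'
#' @param report a `comparison_report`.
#' @param path metrics CSV path.
#' @param errors_path optional path for the per-compound squared-error table.
#' @export
write_comparison_csv <- function(report, path, errors_path = NULL) {
  df <- report$metrics
  names(df)[names(df) == "repeat_"] <- "repeat"
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(errors_path)) {
    edf <- report$errors
    names(edf)[names(edf) == "repeat_"] <- "repeat"
    utils::write.csv(edf, errors_path, row.names = FALSE)
  }
  invisible(path)
}

#' Regularization and training-ratio sweep
#'
#' Grid evaluation of the joint regularization weight (lambda1 = lambda2 =
#' lambda) against the fraction of observed activity cells used for training.
#' For each (ratio, seed) a hold-out set is drawn once per column — the
#' complement of the training ratio, leaving at least 2 observed cells per
#' column — and reused across all lambda values; the fit's RMSE is measured
#' over all held-out cells of all cell lines pooled.
#'
#' @param x an [activity_table()].
#' @param y an aligned [descriptor_table()].
#' @param lambda_grid regularization values; default
#'   `c(0.001, 0.01, 0.1, 1, 10, 100)`.
#' @param train_ratios training fractions of observed cells; default
#'   `c(0.15, 0.35, 0.55, 0.75)`.
#' @param seeds integer seeds over which results are averaged.
#' @param control base [cmf_control()]; its lambdas are overridden by the grid.
#' @return Object of class `sweep_result`: `results` (lambda, ratio, seed,
#'   rmse) and `summary` (lambda x ratio matrix of mean RMSE over seeds).
#' @export
sweep_regularization <- function(x, y,
                                 lambda_grid = c(0.001, 0.01, 0.1, 1, 10, 100),
                                 train_ratios = c(0.15, 0.35, 0.55, 0.75),
                                 seeds = 1:3, control = cmf_control()) {
  pair <- align_tables(x, y)
  x <- pair$activity; y <- pair$descriptors
  m <- nrow(x$values); n <- ncol(x$values)
  rows <- list()
  for (ratio in train_ratios) {
    for (sd_ in seeds) {
      # draw the hold-out cells once per (ratio, seed); shared across lambdas
      held <- with_seed(sd_ * 131071L + round(ratio * 1000), {
        lapply(seq_len(n), function(j) {
          obs <- which(x$mask[, j] == 1)
          n_hold <- min(round((1 - ratio) * length(obs)), length(obs) - 2L)
          if (n_hold < 1L) integer(0) else sample(obs, n_hold)
        })
      })
      x_masked <- x
      for (j in seq_len(n)) if (length(held[[j]]))
        x_masked <- mask_cells(x_masked, held[[j]], j)
      truth <- unlist(lapply(seq_len(n), function(j) x$values[held[[j]], j]))
      for (lam in lambda_grid) {
        ctl <- control
        ctl$lambda1 <- lam; ctl$lambda2 <- lam
        fit <- fit_cmf(x_masked, y, control = ctl, seed = sd_)
        pred_mat <- predict(fit)
        pred <- unlist(lapply(seq_len(n), function(j) pred_mat[held[[j]], j]))
        rows[[length(rows) + 1L]] <- data.frame(lambda = lam, ratio = ratio,
                                                seed = sd_,
                                                rmse = rmse(truth, pred))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary_ <- tapply(results$rmse, list(results$lambda, results$ratio), mean)
  structure(list(results = results, summary = summary_),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result: mean held-out RMSE (rows = lambda, cols = training ratio)\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write sweep results to CSV
#'
#' Writes the lambda x training-ratio matrix of mean RMSE.
#'
#' @param sweep a `sweep_result`.
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- data.frame(lambda = rownames(sweep$summary), sweep$summary,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
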