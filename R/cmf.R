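#' Fitter configuration for collective matrix factorization
#'
#' @param d latent dimension of the shared factor space; must satisfy
#'   `d <= min(m, n, r)`.
#' @param lambda1 weight of the descriptor-reconstruction term (nonnegative).
#' @param lambda2 ridge weight on all three factor matrices (nonnegative).
#' @param max_iter maximum number of outer gradient-descent iterations (T).
#' @param tol absolute objective-decrease stopping threshold (epsilon): the
#'   fit stops once an accepted step decreases the objective by `tol` or less.
#' @param init_scale factors are initialized with uniform draws on
#'   `[0, init_scale]`.
#' @param max_halvings line-search budget: the step size starts at 1 and is
#'   halved at most this many times before the search is declared stalled.
#' @return A list of class `cmf_control`.
#' @export
cmf_control <- function(d = 3, lambda1 = 0.1, lambda2 = 0.1, max_iter = 500,
                        tol = 1e-6, init_scale = 0.1, max_halvings = 50) {
  if (d < 1 || d != round(d)) stopf("d must be a positive integer")
  if (lambda1 < 0 || lambda2 < 0) stopf("lambda1 and lambda2 must be nonnegative")
  if (max_iter < 1) stopf("max_iter must be positive")
  if (tol <= 0) stopf("tol must be positive")
  if (init_scale < 0) stopf("init_scale must be nonnegative")
  if (max_halvings < 1) stopf("max_halvings must be positive")
  structure(list(d = as.integer(d), lambda1 = lambda1, lambda2 = lambda2,
                 max_iter = as.integer(max_iter), tol = tol,
                 init_scale = init_scale, max_halvings = as.integer(max_halvings)),
            class = "cmf_control")
}

#' Initialize factor matrices
#'
#' Fills the compound (U, m x d), cell-line (V, n x d) and descriptor
#' (W, r x d) factors with seeded uniform draws on `[0, init_scale]`.
#' Deterministic given the seed.
#'
#' @param m,n,r problem dimensions (compounds, cell lines, features).
#' @param control a [cmf_control()].
#' @param seed integer RNG seed.
#' @return A `factor_model` list with fields `U`, `V`, `W`, `d`, `lambda1`,
#'   `lambda2`.
#' @export
init_factors <- function(m, n, r, control = cmf_control(), seed) {
  d <- control$d
  if (d > min(m, n, r))
    stopf("latent dimension d=%d exceeds min(m, n, r) = %d", d, min(m, n, r))
  s <- control$init_scale
  with_seed(seed, {
    U <- matrix(stats::runif(m * d, 0, s), m, d)
    V <- matrix(stats::runif(n * d, 0, s), n, d)
    W <- matrix(stats::runif(r * d, 0, s), r, d)
    factor_model(U, V, W, control$lambda1, control$lambda2)
  })
}

#' Construct a factor model
#'
#' @param U m x d compound factor matrix.
#' @param V n x d cell-line factor matrix.
#' @param W r x d descriptor factor matrix.
#' @param lambda1 descriptor-term weight.
#' @param lambda2 ridge weight.
#' @return A list of class `factor_model`.
#' @export
factor_model <- function(U, V, W, lambda1 = 0.1, lambda2 = 0.1) {
  check_matrix(U, "U"); check_matrix(V, "V"); check_matrix(W, "W")
  d <- ncol(U)
  if (ncol(V) != d || ncol(W) != d)
    stopf("U, V, W must share the latent dimension d (got %d, %d, %d)",
          d, ncol(V), ncol(W))
  if (lambda1 < 0 || lambda2 < 0) stopf("lambda weights must be nonnegative")
  structure(list(U = U, V = V, W = W, d = d,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "factor_model")
}

check_cmf_shapes <- function(model, x, y) {
  if (!is_aligned(x, y))
    stopf("tables are not row-aligned; call align_tables() first")
  m <- nrow(x$values); n <- ncol(x$values); r <- ncol(y$values)
  if (nrow(model$U) != m) stopf("U has %d rows, expected m=%d", nrow(model$U), m)
  if (nrow(model$V) != n) stopf("V has %d rows, expected n=%d", nrow(model$V), n)
  if (nrow(model$W) != r) stopf("W has %d rows, expected r=%d", nrow(model$W), r)
  invisible(TRUE)
}

#' Single-matrix factorization objective
#'
#' The plain matrix-completion loss
#' \deqn{\|I \circ (X - UV^T)\|_F^2 + \lambda_1 \|U\|_F^2 + \lambda_2 \|V\|_F^2}
#' where `I` is the observation mask and the circle is the entry-wise product.
#'
#' @param U m x d compound factors.
#' @param V n x d cell-line factors.
#' @param x an [activity_table()].
#' @param lambda1,lambda2 ridge weights on U and V.
#' @return Nonnegative scalar.
#' @export
objective_basic <- function(U, V, x, lambda1 = 0, lambda2 = 0) {
  check_matrix(U, "U"); check_matrix(V, "V")
  if (nrow(U) != nrow(x$values) || nrow(V) != ncol(x$values) || ncol(U) != ncol(V))
    stopf("shape mismatch between factors and activity table")
  R <- x$mask * (observed_values(x) - U %*% t(V))
  fnorm2(R) + lambda1 * fnorm2(U) + lambda2 * fnorm2(V)
}

#' Collective matrix factorization objective
#'
#' The joint loss over the activity matrix X (with observation mask I) and the
#' complete descriptor matrix Y, sharing the compound factors U:
#' \deqn{\tfrac12\|I \circ (X - UV^T)\|_F^2
#'   + \tfrac{\lambda_1}{2}\|Y - UW^T\|_F^2
#'   + \tfrac{\lambda_2}{2}(\|U\|_F^2 + \|V\|_F^2 + \|W\|_F^2)}
#'
#' @param model a [factor_model()].
#' @param x an [activity_table()].
#' @param y a [descriptor_table()] row-aligned with `x`.
#' @return Nonnegative scalar.
#' @export
objective_cmf <- function(model, x, y) {
  check_cmf_shapes(model, x, y)
  R <- x$mask * (observed_values(x) - model$U %*% t(model$V))
  S <- y$values - model$U %*% t(model$W)
  0.5 * fnorm2(R) + 0.5 * model$lambda1 * fnorm2(S) +
    0.5 * model$lambda2 * (fnorm2(model$U) + fnorm2(model$V) + fnorm2(model$W))
}

#' Analytic gradients of the collective objective
#'
#' With `E = I o (UV^T - X)` (residual on observed activity cells) and
#' `F = UW^T - Y` (descriptor residual):
#' grad U = E V + lambda1 F W + lambda2 U;
#' grad V = E^T U + lambda2 V;
#' grad W = lambda1 F^T U + lambda2 W.
#' Y is complete, so no mask enters the descriptor term.
#'
#' @inheritParams objective_cmf
#' @return `list(U =, V =, W =)` of gradient matrices.
#' @export
gradients_cmf <- function(model, x, y) {
  check_cmf_shapes(model, x, y)
  U <- model$U; V <- model$V; W <- model$W
  E <- x$mask * (U %*% t(V) - observed_values(x))
  F_ <- U %*% t(W) - y$values
  list(U = E %*% V + model$lambda1 * (F_ %*% W) + model$lambda2 * U,
       V = t(E) %*% U + model$lambda2 * V,
       W = model$lambda1 * (t(F_) %*% U) + model$lambda2 * W)
}

#' Fit a collective matrix factorization by gradient descent
#'
#' Iteratively minimizes [objective_cmf()]: at each outer iteration the three
#' gradients are computed, a backtracking line search starts at step size
#' gamma = 1 and halves it until the simultaneous update of U, V, W strictly
#' decreases the objective (or the halving budget is exhausted), and the
#' accepted step is applied. Iteration stops when `max_iter` is reached, when
#' the objective decrease falls to `tol` or below, or when the line search
#' stalls. The recorded objective trace is strictly decreasing by
#' construction.
#'
#' @param x an [activity_table()]; cells to be predicted must be masked out.
#' @param y a [descriptor_table()] row-aligned with `x` (complete).
#' @param model0 optional initial [factor_model()]; if `NULL`, factors are
#'   initialized via [init_factors()] (then `seed` is required).
#' @param control a [cmf_control()].
#' @param seed RNG seed for initialization (ignored when `model0` is given).
#' @return An object of class `cmf_fit`: fields `model` (the fitted
#'   [factor_model()]), `trace` (`objective` per iteration including the
#'   initial value, accepted `step_sizes`, `stop_reason` in
#'   `c("max_iter", "tol_reached", "line_search_stalled")`), plus the ids of
#'   the training tables.
#' @examples
#' sim <- simulate_lowrank(m = 20, n = 4, r = 6, d = 2, seed = 1)
#' fit <- fit_cmf(sim$activity, sim$descriptors,
#'                control = cmf_control(d = 2, max_iter = 50), seed = 1)
#' fit$trace$stop_reason
#' @export
fit_cmf <- function(x, y, model0 = NULL, control = cmf_control(), seed = NULL) {
  stopifnot(inherits(x, "activity_table"), inherits(y, "descriptor_table"))
  if (!is_aligned(x, y))
    stopf("tables are not row-aligned; call align_tables() first")
  if (is.null(model0)) {
    if (is.null(seed)) stopf("seed is required when no initial model is given")
    model0 <- init_factors(nrow(x$values), ncol(x$values), ncol(y$values),
                           control, seed)
  }
  check_cmf_shapes(model0, x, y)
  U <- model0$U; V <- model0$V; W <- model0$W
  l1 <- model0$lambda1; l2 <- model0$lambda2
  X0 <- observed_values(x); I <- x$mask; Y <- y$values

  obj_at <- function(U, V, W) {
    0.5 * fnorm2(I * (X0 - U %*% t(V))) +
      0.5 * l1 * fnorm2(Y - U %*% t(W)) +
      0.5 * l2 * (fnorm2(U) + fnorm2(V) + fnorm2(W))
  }

  obj <- obj_at(U, V, W)
  objective <- obj
  step_sizes <- numeric(0)
  stop_reason <- "max_iter"

  for (t in seq_len(control$max_iter)) {
    E <- I * (U %*% t(V) - X0)
    F_ <- U %*% t(W) - Y
    gU <- E %*% V + l1 * (F_ %*% W) + l2 * U
    gV <- t(E) %*% U + l2 * V
    gW <- l1 * (t(F_) %*% U) + l2 * W

    gamma <- 1
    accepted <- FALSE
    for (h in seq_len(control$max_halvings + 1L)) {
      U1 <- U - gamma * gU; V1 <- V - gamma * gV; W1 <- W - gamma * gW
      obj1 <- obj_at(U1, V1, W1)
      if (is.finite(obj1) && obj1 < obj) { accepted <- TRUE; break }
      gamma <- gamma / 2
    }
    if (!accepted) { stop_reason <- "line_search_stalled"; break }

    U <- U1; V <- V1; W <- W1
    step_sizes <- c(step_sizes, gamma)
    objective <- c(objective, obj1)
    decrease <- obj - obj1
    obj <- obj1
    if (decrease <= control$tol) { stop_reason <- "tol_reached"; break }
  }

  model <- factor_model(U, V, W, l1, l2)
  structure(list(model = model,
                 trace = list(objective = objective, step_sizes = step_sizes,
                              stop_reason = stop_reason,
                              iterations = length(step_sizes)),
                 compound_ids = x$compound_ids,
                 cellline_ids = x$cellline_ids,
                 feature_names = y$feature_names,
                 control = control),
            class = "cmf_fit")
}

#' @export
print.cmf_fit <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("cmf_fit: d=%d, %d iterations, objective %.6g -> %.6g (%s)\n",
              x$model$d, tr$iterations, tr$objective[1],
              tr$objective[length(tr$objective)], tr$stop_reason))
  invisible(x)
}

#' Predict the completed activity matrix
#'
#' Returns `U V^T`, the model's reconstruction of the activity matrix; callers
#' pick out the masked (held-out or genuinely missing) cells.
#'
#' @param object a `cmf_fit` or `factor_model`.
#' @param ... unused.
#' @return m x n numeric matrix with compound/cell-line dimnames when fitted
#'   through [fit_cmf()].
#' @export
predict.cmf_fit <- function(object, ...) {
  p <- object$model$U %*% t(object$model$V)
  dimnames(p) <- list(object$compound_ids, object$cellline_ids)
  p
}

#' @rdname predict.cmf_fit
#' @export
predict.factor_model <- function(object, ...) object$U %*% t(object$V)

#' Serialize a factor model to JSON
#'
#' Stores d, the two lambda weights, ids when available, and the three factor
#' matrices row-major at full double precision (round trip exact).
#'
#' @param object a `cmf_fit` or [factor_model()].
#' @param path output JSON path.
#' @export
write_cmf_model <- function(object, path) {
  model <- if (inherits(object, "cmf_fit")) object$model else object
  stopifnot(inherits(model, "factor_model"))
  doc <- list(d = model$d, lambda1 = model$lambda1, lambda2 = model$lambda2,
              m = nrow(model$U), n = nrow(model$V), r = nrow(model$W),
              compound_ids = if (inherits(object, "cmf_fit")) object$compound_ids,
              cellline_ids = if (inherits(object, "cmf_fit")) object$cellline_ids,
              feature_names = if (inherits(object, "cmf_fit")) object$feature_names,
              U = as.vector(t(model$U)), V = as.vector(t(model$V)),
              W = as.vector(t(model$W)))
  doc <- doc[!vapply(doc, is.null, logical(1))]
  # 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a factor model from JSON
#'
#' @param path JSON path written by [write_cmf_model()].
#' @return A `cmf_fit`-like object if ids were stored, otherwise a bare
#'   [factor_model()].
#' @export
read_cmf_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- factor_model(
    matrix(doc$U, doc$m, doc$d, byrow = TRUE),
    matrix(doc$V, doc$n, doc$d, byrow = TRUE),
    matrix(doc$W, doc$r, doc$d, byrow = TRUE),
    doc$lambda1, doc$lambda2)
  if (!is.null(doc$compound_ids)) {
    structure(list(model = model, trace = NULL,
                   compound_ids = doc$compound_ids,
                   cellline_ids = doc$cellline_ids,
                   feature_names = doc$feature_names,
                   control = NULL),
              class = "cmf_fit")
  } else {
    model
  }
}

# mask held-out cells (rows within one column) of an activity table
mask_cells <- function(x, rows, col) {
  mask <- x$mask; values <- x$values
  mask[rows, col] <- 0
  values[rows, col] <- NA_real_
  activity_table(values, x$compound_ids, x$cellline_ids, mask = mask)
}
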