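# Independent oracles: deliberately plain scalar-loop implementations, kept
# free of the package's matrix code paths so they can arbitrate.

# joint objective evaluated cell by cell
oracle_objective_cmf <- function(model, x, y) {
  U <- model$U; V <- model$V; W <- model$W
  m <- nrow(U); n <- nrow(V); r <- nrow(W); d <- ncol(U)
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (x$mask[i, j] == 1) {
      pred <- 0
      for (k in seq_len(d)) pred <- pred + U[i, k] * V[j, k]
      acc <- acc + 0.5 * (x$values[i, j] - pred)^2
    }
  }
  for (i in seq_len(m)) for (j in seq_len(r)) {
    pred <- 0
    for (k in seq_len(d)) pred <- pred + U[i, k] * W[j, k]
    acc <- acc + 0.5 * model$lambda1 * (y$values[i, j] - pred)^2
  }
  reg <- sum(U^2) + sum(V^2) + sum(W^2)
  acc + 0.5 * model$lambda2 * reg
}

# central finite differences of objective_cmf wrt one factor matrix
oracle_fd_gradient <- function(model, x, y, which, h = 1e-6) {
  M <- model[[which]]
  G <- matrix(0, nrow(M), ncol(M))
  for (i in seq_along(M)) {
    mp <- model; mp[[which]][i] <- M[i] + h
    mm <- model; mm[[which]][i] <- M[i] - h
    G[i] <- (objective_cmf(mp, x, y) - objective_cmf(mm, x, y)) / (2 * h)
  }
  G
}

# exhaustive greedy maximin ranking: plain double loop, own z-scoring
oracle_maximin_ranking <- function(M) {
  m <- nrow(M)
  Z <- M
  for (j in seq_len(ncol(M))) {
    s <- sd(M[, j])
    Z[, j] <- if (s > 0) (M[, j] - mean(M[, j])) / s else 0
  }
  dist_ij <- function(a, b) sqrt(sum((Z[a, ] - Z[b, ])^2))
  ranked <- 1L
  while (length(ranked) < m) {
    best <- NA_integer_; best_score <- -Inf
    for (cand in setdiff(seq_len(m), ranked)) {
      dmin <- Inf
      for (rk in ranked) dmin <- min(dmin, dist_ij(cand, rk))
      if (dmin > best_score) { best_score <- dmin; best <- cand }
    }
    ranked <- c(ranked, best)
  }
  ranked
}

oracle_rmse <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + (obs[i] - pred[i])^2
  sqrt(acc / length(obs))
}

oracle_r_squared <- function(obs, pred) {
  mu <- sum(obs) / length(obs)
  ss_err <- 0; ss_tot <- 0
  for (i in seq_along(obs)) {
    ss_err <- ss_err + (obs[i] - pred[i])^2
    ss_tot <- ss_tot + (obs[i] - mu)^2
  }
  1 - ss_err / ss_tot
}

# small random aligned tables for property loops
random_instance <- function(m, n, r, d, missing = 0.2, seed = 1) {
  simulate_lowrank(m, n, r, d, noise_sd_x = 0.3, noise_sd_y = 0.3,
                   missing_fraction = missing, seed = seed)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
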