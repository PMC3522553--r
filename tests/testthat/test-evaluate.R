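test_that("rmse and r_squared match their closed forms and scalar oracles", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 5)), -1)
  expect_equal(rmse(1:4, 1:4), 0)
  expect_equal(r_squared(1:4, 1:4), 1)
  # predicting the mean gives R^2 = 0; a constant offset gives RMSE = |c|
  obs <- c(2, 4, 9, 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(rmse(obs, obs + 1.7), 1.7)
  expect_error(rmse(1:3, 1:2), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1, 1), "at least 2")

  for (i in 1:100) {
    v <- withr::with_seed(i, list(o = rnorm(sample(2:30, 1)), p = NULL))
    v$p <- withr::with_seed(i + 1000, v$o + rnorm(length(v$o)))
    expect_equal(rmse(v$o, v$p), oracle_rmse(v$o, v$p), tolerance = 1e-12)
    if (sd(v$o) > 0)
      expect_equal(r_squared(v$o, v$p), oracle_r_squared(v$o, v$p),
                   tolerance = 1e-12)
  }
})

test_that("r_squared is 1 exactly when rmse is 0 on non-constant data", {
  for (i in 1:20) {
    o <- withr::with_seed(i, rnorm(10))
    p <- withr::with_seed(i + 99, o + rnorm(10) * rbinom(1, 1, 0.5))
    expect_equal(rmse(o, p) == 0, r_squared(o, p) == 1)
  }
})

test_that("fit_ridge solves the unpenalized-intercept normal equations", {
  # 3-point 1-D instance, alpha = 1, solved by hand via the 2x2 system
  x <- c(1, 2, 4); y <- c(1, 2, 2)
  A <- rbind(c(3, sum(x)), c(sum(x), sum(x^2) + 1))
  sol <- solve(A, c(sum(y), sum(x * y)))
  fit <- fit_ridge(matrix(x), y, alpha = 1, standardize = FALSE)
  expect_equal(unname(fit$coef), sol[2], tolerance = 1e-12)
  expect_equal(fit$intercept - fit$coef * fit$center, sol[1],
               tolerance = 1e-12, ignore_attr = TRUE)

  # exact linear data with alpha = 0 and full rank reproduces the truth
  X <- matrix(rnorm(30), 10, 3)
  yy <- drop(X %*% c(1, -2, 0.5)) + 3
  f0 <- fit_ridge(X, yy, alpha = 0, standardize = FALSE)
  expect_equal(max(abs(predict(f0, X) - yy)), 0, tolerance = 1e-8)

  # huge penalty shrinks to the mean predictor
  fbig <- fit_ridge(X, yy, alpha = 1e12)
  expect_equal(max(abs(predict(fbig, X) - mean(yy))), 0, tolerance = 1e-6)

  # rank-deficient design with alpha = 0 is rejected with advice
  Xs <- cbind(1:4, 1:4)
  expect_error(fit_ridge(Xs, rnorm(4), alpha = 0), "alpha > 0")
  expect_error(fit_ridge(matrix(1, 1, 1), 1), "at least 2")
})

test_that("run_comparison fills the protocol grid fairly and without leakage", {
  sim <- simulate_shared_latent(m = 30, n = 3, d = 2, cross_column_signal = 0.8,
                                seed = 14)
  ctl <- cmf_control(d = 2, max_iter = 80)
  rep3 <- suppressWarnings(
    run_comparison(sim$activity, sim$descriptors, protocol = "random",
                   repeats = 3, seed = 14, methods = c("cmf", "ridge", "svr"),
                   control = ctl))
  grid <- table(rep3$metrics$method, rep3$metrics$repeat_)
  expect_true(all(grid == 3)) # every method x repeat covers the 3 cell lines
  expect_equal(sort(unique(rep3$metrics$repeat_)), 1:3)
  # identical test cells across methods within a (cell line, repeat)
  key <- function(mth) {
    e <- rep3$errors
    e <- e[e$method == mth, c("cell_line", "repeat_", "compound_id")]
    e[order(e$cell_line, e$repeat_, e$compound_id), ]
  }
  expect_equal(key("cmf"), key("ridge"), ignore_attr = TRUE)
  expect_equal(key("cmf"), key("svr"), ignore_attr = TRUE)

  # determinism: same seed, same numbers
  rep3b <- suppressWarnings(
    run_comparison(sim$activity, sim$descriptors, protocol = "random",
                   repeats = 3, seed = 14, methods = c("cmf", "ridge", "svr"),
                   control = ctl))
  expect_identical(rep3b$metrics, rep3$metrics)

  # no test-cell leakage: CMF predictions ignore the values of masked cells,
  # so altering them (before masking) cannot change anything
  plan <- random_split(30, 1 / 3, seed = 14)
  x <- sim$activity
  x_masked <- cmfqsar:::mask_cells(x, plan$test, 1)
  vals2 <- x$values; vals2[plan$test, 1] <- 0
  x2 <- activity_table(vals2, x$compound_ids, x$cellline_ids)
  x2_masked <- cmfqsar:::mask_cells(x2, plan$test, 1)
  f1 <- fit_cmf(x_masked, sim$descriptors, control = ctl, seed = 1)
  f2 <- fit_cmf(x2_masked, sim$descriptors, control = ctl, seed = 1)
  expect_identical(predict(f1), predict(f2))

  # diverse protocol produces the single deterministic partition
  repd <- suppressWarnings(
    run_comparison(sim$activity, sim$descriptors, protocol = "diverse_subset",
                   methods = c("cmf", "ridge"), control = ctl, seed = 1))
  expect_equal(unique(repd$metrics$repeat_), 1L)
  expect_equal(repd$protocol, "diverse_subset")
})

test_that("CMF beats per-column ridge when columns share latent structure", {
  wins <- 0L
  for (s in 1:10) {
    sim <- simulate_shared_latent(m = 90, n = 4, d = 2,
                                  cross_column_signal = 0.9, seed = s)
    rep1 <- suppressWarnings(
      run_comparison(sim$activity, sim$descriptors, protocol = "random",
                     repeats = 1, seed = s, methods = c("cmf", "ridge"),
                     control = cmf_control(d = 2, max_iter = 300)))
    agg <- stats::aggregate(rmse ~ method, rep1$metrics, mean)
    if (agg$rmse[agg$method == "cmf"] < agg$rmse[agg$method == "ridge"])
      wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("method_significance reports a paired Wilcoxon p-value per baseline", {
  sim <- simulate_shared_latent(m = 40, n = 2, d = 2, cross_column_signal = 0.9,
                                seed = 31)
  rep5 <- suppressWarnings(
    run_comparison(sim$activity, sim$descriptors, protocol = "random",
                   repeats = 5, seed = 31, methods = c("cmf", "ridge"),
                   control = cmf_control(d = 2, max_iter = 100)))
  sig <- method_significance(rep5)
  expect_equal(nrow(sig), 2L) # 2 cell lines x 1 baseline
  expect_true(all(sig$p_value >= 0 & sig$p_value <= 1, na.rm = TRUE))
})

test_that("sweep_regularization emits the full grid and favors more training data", {
  sim <- simulate_lowrank(40, 4, 8, 2, noise_sd_x = 0.1, noise_sd_y = 0.1,
                          seed = 17)
  sw <- sweep_regularization(sim$activity, sim$descriptors, seeds = 1:2,
                             control = cmf_control(d = 2, max_iter = 150))
  expect_equal(dim(sw$summary), c(6L, 4L))
  expect_equal(as.numeric(rownames(sw$summary)), c(0.001, 0.01, 0.1, 1, 10, 100))
  expect_equal(as.numeric(colnames(sw$summary)), c(0.15, 0.35, 0.55, 0.75))
  expect_lte(median(sw$results$rmse[sw$results$ratio == 0.75]),
             median(sw$results$rmse[sw$results$ratio == 0.15]))
  sw2 <- sweep_regularization(sim$activity, sim$descriptors, seeds = 1:2,
                              control = cmf_control(d = 2, max_iter = 150))
  expect_identical(sw2$results, sw$results)
})
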