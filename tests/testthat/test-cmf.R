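test_that("factor initialization is seeded, bounded, and dimension-checked", {
  ctl <- cmf_control(d = 2, init_scale = 0.5)
  a <- init_factors(6, 4, 3, ctl, seed = 9)
  b <- init_factors(6, 4, 3, ctl, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$U >= 0 & a$U <= 0.5))
  z <- init_factors(6, 4, 3, cmf_control(d = 2, init_scale = 0), seed = 1)
  expect_true(all(z$U == 0) && all(z$V == 0) && all(z$W == 0))
  expect_error(init_factors(5, 4, 3, cmf_control(d = 4), seed = 1), "exceeds")
})

test_that("objective_basic matches hand evaluation", {
  x <- activity_table(matrix(c(1, 3, 2, 4), 2, 2)) # [[1,2],[3,4]]
  U <- matrix(1, 2, 1); V <- matrix(1, 2, 1)
  # residuals [[0,1],[2,3]] -> 14; ||U||_F^2 = ||V||_F^2 = 2, so + 2 + 2
  expect_equal(objective_basic(U, V, x, 1, 1), 18)
  expect_equal(objective_basic(0 * U, 0 * V, x, 0, 0), sum(x$values^2))
  expect_equal(objective_basic(U, V, activity_table(U %*% t(V)), 0, 0), 0)
  expect_error(objective_basic(matrix(1, 3, 1), V, x), "mismatch")
})

test_that("objective_cmf agrees with a scalar-loop oracle", {
  for (seed in 1:5) {
    sim <- random_instance(4, 3, 2, 2, missing = 0.25, seed = seed)
    mod <- init_factors(4, 3, 2, cmf_control(d = 2, lambda1 = 0.3, lambda2 = 0.7),
                        seed = seed + 100)
    expect_equal(objective_cmf(mod, sim$activity, sim$descriptors),
                 oracle_objective_cmf(mod, sim$activity, sim$descriptors),
                 tolerance = 1e-12)
  }
  # exact joint fit with no regularization is a zero of the objective
  sim <- simulate_lowrank(6, 3, 4, 2, seed = 1)
  mod <- factor_model(sim$truth$U, sim$truth$V, sim$truth$W,
                      lambda1 = 1, lambda2 = 0)
  expect_equal(objective_cmf(mod, sim$activity, sim$descriptors), 0)
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:20) {
    dims <- withr::with_seed(seed, c(m = sample(4:10, 1), n = sample(2:4, 1),
                                     r = sample(2:6, 1)))
    d <- min(3, dims["n"], dims["r"])
    sim <- random_instance(dims["m"], dims["n"], dims["r"], d,
                           missing = 0.2, seed = seed)
    mod <- init_factors(dims["m"], dims["n"], dims["r"],
                        cmf_control(d = d, lambda1 = 0.4, lambda2 = 0.2,
                                    init_scale = 1), seed = seed + 500)
    g <- gradients_cmf(mod, sim$activity, sim$descriptors)
    for (nm in c("U", "V", "W")) {
      fd <- oracle_fd_gradient(mod, sim$activity, sim$descriptors, nm)
      expect_lt(max(abs(g[[nm]] - fd)) / max(1, max(abs(fd))), 1e-5)
    }
  }
})

test_that("gradients vanish at an exact joint fit and without data terms", {
  sim <- simulate_lowrank(6, 3, 4, 2, seed = 2)
  mod <- factor_model(sim$truth$U, sim$truth$V, sim$truth$W,
                      lambda1 = 2.5, lambda2 = 0)
  g <- gradients_cmf(mod, sim$activity, sim$descriptors)
  for (nm in c("U", "V", "W")) expect_equal(max(abs(g[[nm]])), 0)

  # empty mask and lambda1 = 0 leave no force on V
  x_empty <- activity_table(matrix(NA_real_, 6, 3),
                            compound_ids = sim$activity$compound_ids,
                            cellline_ids = sim$activity$cellline_ids)
  mod0 <- factor_model(mod$U, mod$V, mod$W, lambda1 = 0, lambda2 = 0)
  g0 <- gradients_cmf(mod0, x_empty, sim$descriptors)
  expect_true(all(g0$V == 0))
})

test_that("fit_cmf descends monotonically and honors the stopping rules", {
  sim <- random_instance(15, 4, 6, 2, seed = 8)
  fit <- fit_cmf(sim$activity, sim$descriptors,
                 control = cmf_control(d = 2, max_iter = 60), seed = 8)
  expect_true(all(diff(fit$trace$objective) < 0))
  expect_equal(length(fit$trace$step_sizes), fit$trace$iterations)
  expect_true(fit$trace$stop_reason %in%
                c("max_iter", "tol_reached", "line_search_stalled"))

  one <- fit_cmf(sim$activity, sim$descriptors,
                 control = cmf_control(d = 2, max_iter = 1), seed = 8)
  expect_equal(one$trace$iterations, 1L)
  expect_equal(one$trace$stop_reason, "max_iter")

  tight <- fit_cmf(sim$activity, sim$descriptors,
                   control = cmf_control(d = 2, max_iter = 5000, tol = 1e-4),
                   seed = 8)
  n_obj <- length(tight$trace$objective)
  expect_equal(tight$trace$stop_reason, "tol_reached")
  expect_lte(tight$trace$objective[n_obj - 1] - tight$trace$objective[n_obj], 1e-4)
})

test_that("noiseless shared-factor data is recovered almost exactly", {
  sim <- simulate_lowrank(30, 4, 6, 2, seed = 21)
  ctl <- cmf_control(d = 2, lambda1 = 1, lambda2 = 1e-6,
                     max_iter = 4000, tol = 1e-12)
  fit <- fit_cmf(sim$activity, sim$descriptors, control = ctl, seed = 21)
  expect_lt(tail(fit$trace$objective, 1), 1e-4 * fit$trace$objective[1])
  expect_lt(max(abs(predict(fit) - sim$truth$X_clean)), 1e-2)
})

test_that("permuting compound rows permutes fitted factors and not the trace", {
  sim <- random_instance(10, 3, 4, 2, seed = 4)
  perm <- withr::with_seed(99, sample(10))
  x <- sim$activity; y <- sim$descriptors
  xp <- activity_table(x$values[perm, ], x$compound_ids[perm], x$cellline_ids,
                       mask = x$mask[perm, ])
  yp <- descriptor_table(y$values[perm, ], y$compound_ids[perm],
                         y$feature_names, y$kinds)
  ctl <- cmf_control(d = 2, max_iter = 40)
  m0 <- init_factors(10, 3, 4, ctl, seed = 5)
  m0p <- factor_model(m0$U[perm, ], m0$V, m0$W, m0$lambda1, m0$lambda2)
  fit <- fit_cmf(x, y, model0 = m0, control = ctl)
  fitp <- fit_cmf(xp, yp, model0 = m0p, control = ctl)
  expect_equal(fitp$trace$objective, fit$trace$objective)
  expect_equal(fitp$model$U, fit$model$U[perm, ])
  expect_equal(fitp$model$V, fit$model$V)
})

test_that("with lambda1 = 0 and W = 0 the data term reduces to the basic model", {
  sim <- random_instance(8, 3, 4, 2, seed = 6)
  m0 <- init_factors(8, 3, 4, cmf_control(d = 2, lambda1 = 0, lambda2 = 0.1),
                     seed = 7)
  m0$W[] <- 0
  # Eq.(5) with lambda1=0 and W=0 equals half the Eq.(3) value at equal lambdas
  expect_equal(objective_cmf(m0, sim$activity, sim$descriptors),
               0.5 * objective_basic(m0$U, m0$V, sim$activity, 0.1, 0.1))
  g <- gradients_cmf(m0, sim$activity, sim$descriptors)
  expect_true(all(g$W == 0.1 * m0$W)) # only the ridge term acts on W
})

test_that("predict returns the factor outer product", {
  mod <- factor_model(matrix(c(2, 3), 2, 1), matrix(c(1, 4), 2, 1),
                      matrix(1, 2, 1))
  expect_equal(predict(mod), matrix(c(2, 3, 8, 12), 2, 2))
  mod0 <- factor_model(matrix(0, 2, 1), matrix(0, 2, 1), matrix(0, 2, 1))
  expect_true(all(predict(mod0) == 0))
})

test_that("model JSON serialization round-trips exactly", {
  sim <- random_instance(7, 3, 4, 2, seed = 13)
  fit <- fit_cmf(sim$activity, sim$descriptors,
                 control = cmf_control(d = 2, max_iter = 20), seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_cmf_model(fit, path)
  back <- read_cmf_model(path)
  expect_equal(back$model$U, fit$model$U, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$model$V, fit$model$V, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$model$W, fit$model$W, tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(back$model$lambda1, fit$model$lambda1)
  expect_identical(back$compound_ids, fit$compound_ids)
  expect_equal(predict(back), predict(fit), tolerance = 1e-15,
               ignore_attr = TRUE)
})
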