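sphere_bounds <- data.frame(name = c("x1", "x2"), lower = -5, upper = 5,
                            log = FALSE)

test_that("the hybrid optimizer solves the sphere and is seed-deterministic", {
  r1 <- pso_minimize(function(p) sum(p^2), sphere_bounds,
                     pso_config(seed = 42))
  expect_lt(r1$best_value, 1e-3)
  expect_true(all(diff(r1$trajectory) <= 1e-15))
  r2 <- pso_minimize(function(p) sum(p^2), sphere_bounds,
                     pso_config(seed = 42))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$best_par, r2$best_par)
  r3 <- pso_minimize(function(p) sum(p^2), sphere_bounds,
                     pso_config(seed = 43))
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("an optimum on the boundary is found at the bound", {
  b <- data.frame(name = "x", lower = -5, upper = 5, log = FALSE)
  r <- pso_minimize(function(p) (p[["x"]] - 10)^2, b, pso_config(seed = 7))
  expect_equal(unname(r$best_par), 5, tolerance = 1e-6)
})

test_that("pattern search polls to the optimum and never regresses", {
  b <- data.frame(name = "x", lower = -10, upper = 10, log = FALSE)
  at_opt <- pattern_search_refine(function(p) (p[["x"]])^2, c(x = 0), b,
                                  pso_config(ps_tolerance = 1e-5))
  expect_equal(unname(at_opt$par), 0)
  vshape <- pattern_search_refine(function(p) abs(p[["x"]] - 2), c(x = 0), b,
                                  pso_config(ps_tolerance = 1e-5))
  expect_equal(unname(vshape$par), 2, tolerance = 2e-3)
  # monotone contract on the sphere: refinement cannot exceed the PSO best
  r <- pso_minimize(function(p) sum(p^2), sphere_bounds, pso_config(seed = 1))
  expect_equal(r$best_value, min(r$trajectory))
})

test_that("the objective must be finite somewhere", {
  b <- data.frame(name = "x", lower = 0, upper = 1, log = FALSE)
  expect_error(pso_minimize(function(p) NA_real_, b, pso_config(seed = 1)),
               "non-finite")
})

test_that("the search box contains exactly the licensed parameters", {
  expect_setequal(nirsense:::svr_search_bounds("epsilon", "linear")$name,
                  c("C", "epsilon"))
  expect_setequal(nirsense:::svr_search_bounds("epsilon", "radial_base")$name,
                  c("C", "epsilon", "gamma"))
  expect_setequal(nirsense:::svr_search_bounds("nu", "sigmoid")$name,
                  c("C", "nu", "gamma", "coef0"))
  expect_setequal(nirsense:::svr_search_bounds("epsilon", "polynomial")$name,
                  c("C", "epsilon", "gamma", "coef0", "degree"))
})

test_that("tuning searches only licensed dimensions and reports them", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] + 0.05 * rnorm(20)
  cfg <- pso_config(swarm_size = 6, max_iterations = 6, patience = 3,
                    ps_tolerance = 0.02, seed = 5)
  lin <- tune_svr(X, y, "epsilon", "linear", cfg, cv_seed = 2)
  expect_setequal(names(lin$best_par), c("C", "epsilon"))
  expect_null(lin$best_spec$gamma)
  rbf <- tune_svr(X, y, "epsilon", "radial_base", cfg, cv_seed = 2)
  expect_setequal(names(rbf$best_par), c("C", "epsilon", "gamma"))
  expect_true(all(diff(rbf$trajectory) <= 1e-15))
  expect_equal(rbf$best_rmsecv, rbf$trajectory[length(rbf$trajectory)])
})

test_that("tuning a noiseless linear relation reaches near-interpolation", {
  x <- matrix(seq(0, 9), ncol = 1)
  y <- 2 * x[, 1] + 1
  tr <- tune_svr(x, y, "epsilon", "linear",
                 pso_config(swarm_size = 10, max_iterations = 20,
                            patience = 8, seed = 3), cv_seed = 4, k = 5)
  expect_lt(tr$best_rmsecv, 0.01 * sd(y))
  # direct verification that the bound is attainable: large C, small epsilon
  direct <- kfold_rmsecv(x, y, svr_spec("epsilon", "linear", C = 100,
                                        epsilon = 1e-3),
                         folds = make_folds(10, 5, 4))
  expect_lt(direct, 0.01 * sd(y))
})

test_that("tuning runs are reproducible and share folds across candidates", {
  set.seed(9)
  X <- matrix(rnorm(40), 20, 2)
  y <- sin(X[, 1]) + 0.05 * rnorm(20)
  cfg <- pso_config(swarm_size = 5, max_iterations = 5, patience = 3,
                    ps_tolerance = 0.05, seed = 11)
  t1 <- tune_svr(X, y, config = cfg, cv_seed = 12)
  t2 <- tune_svr(X, y, config = cfg, cv_seed = 12)
  expect_identical(t1$trajectory, t2$trajectory)
  expect_identical(t1$best_par, t2$best_par)
  # the reported optimum is reproducible from its spec on the same folds
  expect_equal(kfold_rmsecv(X, y, t1$best_spec,
                            folds = make_folds(20, 5, 12)),
               t1$best_rmsecv, tolerance = 1e-12)
})
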