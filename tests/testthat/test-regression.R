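test_that("epsilon-SVR fits noiseless linear data within the tube", {
  x <- matrix(0:9, ncol = 1)
  y <- 2 * x[, 1] + 1
  spec <- svr_spec("epsilon", "linear", C = 1e3, epsilon = 0.01)
  m <- fit_svr(x, y, spec)
  expect_lt(max(abs(predict(m, x) - y)), 0.01 + 1e-3)
})

test_that("the solver agrees with an independent SVR implementation", {
  # kernlab solves the same eps-SVR dual with a different QP engine
  set.seed(21)
  X <- matrix(rnorm(60), 20, 3)
  y <- X[, 1] - 0.5 * X[, 2] + 0.1 * rnorm(20)
  spec <- svr_spec("epsilon", "radial_base", C = 10, epsilon = 0.05,
                   gamma = 0.3)
  mine <- predict(fit_svr(X, y, spec), X)
  ref <- kernlab::ksvm(X, y, type = "eps-svr", C = 10, epsilon = 0.05,
                       kernel = "rbfdot",
                       kpar = list(sigma = 0.3), scaled = FALSE)
  expect_equal(mine, as.numeric(kernlab::predict(ref, X)), tolerance = 0.02)
})

test_that("degenerate and limiting SVR cases behave as the dual dictates", {
  x <- matrix(seq(0, 1, length.out = 8), ncol = 1)
  const <- fit_svr(x, rep(3, 8), svr_spec("epsilon", "radial_base", C = 1,
                                          epsilon = 0.1, gamma = 1))
  expect_true(all(abs(predict(const, x) - 3) <= 0.1 + 1e-6))
  # epsilon wider than the response range: empty dual, constant prediction
  y <- sin(4 * x[, 1])
  wide <- fit_svr(x, y, svr_spec("epsilon", "radial_base", C = 10,
                                 epsilon = 5, gamma = 1))
  p <- predict(wide, x)
  expect_equal(diff(range(p)), 0)
  expect_true(all(abs(p - y) <= 5 + 1e-6))
})

test_that("SVR fits are deterministic and row-local in prediction", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  spec <- svr_spec("nu", "radial_base", C = 5, nu = 0.5, gamma = 0.2)
  m1 <- fit_svr(X, y, spec)
  m2 <- fit_svr(X, y, spec)
  expect_identical(predict(m1, X), predict(m2, X))
  perm <- c(4, 1, 3, 2, 5, 10, 7, 9, 6, 8)
  expect_identical(predict(m1, X[perm, ]), predict(m1, X)[perm])
  expect_error(predict(m1, X[, 1:3]), "expected 4 channels")
  Xbad <- X; Xbad[2, 2] <- NA
  expect_error(fit_svr(Xbad, y, spec), "non-finite")
})

test_that("an all-zero channel does not change epsilon-SVR predictions", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  spec <- svr_spec("epsilon", "radial_base", C = 2, epsilon = 0.05,
                   gamma = 0.4)
  base <- predict(fit_svr(X, y, spec), X)
  aug <- cbind(X, 0)
  expect_equal(predict(fit_svr(aug, y, spec), aug), base, tolerance = 1e-10)
})

test_that("the spec constructor licenses exactly the allowed parameters", {
  expect_error(svr_spec("epsilon", "linear", C = 1, epsilon = 0.1, gamma = 1),
               "except the linear")
  expect_error(svr_spec("epsilon", "radial_base", C = 1, epsilon = 0.1),
               "gamma")
  expect_error(svr_spec("epsilon", "radial_base", C = 1, epsilon = 0.1,
                        nu = 0.5, gamma = 1), "nu is licensed")
  expect_error(svr_spec("nu", "radial_base", C = 1, nu = 0.5, gamma = 1,
                        degree = 3), "polynomial")
  expect_error(svr_spec("epsilon", "polynomial", C = 1, epsilon = 0.1,
                        gamma = 1, degree = 7), "2\\.\\.5")
  ok <- svr_spec("epsilon", "polynomial", C = 1, epsilon = 0.1, gamma = 1,
                 degree = 3, coef0 = 0.5)
  expect_s3_class(ok, "svr_spec")
})

test_that("PLS recovers exact linear structure and matches OLS at full rank", {
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5)
  beta <- c(1, -2, 0.5, 0, 3)
  y <- drop(X %*% beta) + 4
  # rank-1 X with y along its single latent direction: one component is exact
  tvec <- rnorm(20)
  X1 <- outer(tvec, c(0.5, 1, -1, 2, 0.3))
  y1 <- 2 * tvec + 1
  one <- fit_pls(X1, y1, n_components = 1)
  expect_lt(rmse(y1, predict(one, X1)), 1e-8)
  full <- fit_pls(X, y, n_components = 5)
  ols <- fitted(lm(y ~ X))
  expect_equal(predict(full, X), unname(ols), tolerance = 1e-8)
  expect_error(fit_pls(X, y, n_components = 0), "n_components")
  expect_error(pls_spec(0), "n_components")
})

test_that("RMSECV uses the pooled convention and matches a hand-rolled loop", {
  set.seed(6)
  X <- matrix(rnorm(36), 12, 3)
  y <- drop(X %*% c(1, 2, -1)) + 0.1 * rnorm(12)
  spec <- svr_spec("epsilon", "radial_base", C = 10, epsilon = 0.01,
                   gamma = 0.3)
  folds <- make_folds(12, 4, seed = 31)
  # brute-force oracle: explicit loop over the enumerated folds
  se <- numeric(0)
  per_fold <- numeric(0)
  for (f in folds) {
    m <- fit_svr(X[-f, , drop = FALSE], y[-f], spec)
    e2 <- (predict(m, X[f, , drop = FALSE]) - y[f])^2
    se <- c(se, e2)
    per_fold <- c(per_fold, sqrt(mean(e2)))
  }
  expect_equal(kfold_rmsecv(X, y, spec, folds = folds), sqrt(mean(se)),
               tolerance = 1e-12)
  expect_equal(kfold_rmsecv(X, y, spec, folds = folds, pooled = FALSE),
               mean(per_fold), tolerance = 1e-12)
  # a near-interpolating model scores near zero
  lin <- svr_spec("epsilon", "linear", C = 1e4, epsilon = 1e-4)
  ylin <- drop(X %*% c(1, 2, -1))
  expect_lt(kfold_rmsecv(X, ylin, lin, folds = folds), 0.05 * sd(ylin))
})

test_that("fold assignment is a deterministic partition and validates k", {
  f1 <- make_folds(11, 4, seed = 9)
  f2 <- make_folds(11, 4, seed = 9)
  expect_identical(f1, f2)
  expect_setequal(unlist(f1), 1:11)
  expect_true(all(abs(lengths(f1) - 11 / 4) < 1))
  expect_error(make_folds(3, 5, seed = 1), "exceeds")
  expect_error(kfold_rmsecv(matrix(rnorm(6), 3), rnorm(3),
                            svr_spec("epsilon", "linear", C = 1,
                                     epsilon = 0.1), k = 5), "exceeds")
})
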