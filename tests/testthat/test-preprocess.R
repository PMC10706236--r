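test_that("smoothing spline limits: p -> 1 interpolates, p -> 0 gives the OLS line", {
  set.seed(1)
  x <- seq(4000, 4800, 20)
  y <- 2 + 0.001 * x + rnorm(length(x), 0, 0.05)
  M <- matrix(y, 1, dimnames = list(NULL, x))
  expect_equal(as.numeric(smooth_spectra(M, 1 - 1e-12)), y, tolerance = 1e-8)
  line <- fitted(lm(y ~ x))
  expect_equal(as.numeric(smooth_spectra(M, 1e-11)), unname(line),
               tolerance = 1e-4)
  expect_error(smooth_spectra(M, 0), "\\(0, 1\\]")
  expect_error(smooth_spectra(M, 1.5), "\\(0, 1\\]")
})

test_that("smoothing spline matches the direct penalized-spline solution", {
  set.seed(3)
  x <- seq(0, 100, length.out = 41)
  y <- sin(x / 15) + rnorm(41, 0, 0.1)
  M <- matrix(y, 1, dimnames = list(NULL, x))
  for (p in c(0.3, 0.01)) {
    expect_equal(as.numeric(smooth_spectra(M, p)), reinsch_spline(x, y, p),
                 tolerance = 5e-4)
  }
})

test_that("a noise-free Gaussian band passes through p = 0.01 nearly unchanged", {
  wn <- seq(4000, 10000, 4)
  band <- exp(-(wn - 6000)^2 / (2 * 200^2))
  M <- matrix(band, 1, dimnames = list(NULL, wn))
  expect_lt(max(abs(smooth_spectra(M, 0.01) - M)), 1e-4)
})

test_that("MSC inverts affine scatter and is idempotent with a fixed reference", {
  set.seed(2)
  ref <- exp(-(seq(-3, 3, length.out = 50))^2) + 0.2
  row <- 2 * ref + 1
  out <- msc(rbind(row, row), reference = ref)
  expect_equal(unname(out$spectra[1, ]), ref, tolerance = 1e-12)
  # identity case
  same <- msc(rbind(ref, ref), reference = ref)
  expect_equal(unname(same$spectra[1, ]), ref, tolerance = 1e-12)
  # idempotence when the same reference is reused
  X <- matrix(rnorm(5 * 50, sd = 0.1), 5) + rep(ref, each = 5)
  once <- msc(X, reference = ref)$spectra
  twice <- msc(once, reference = ref)$spectra
  expect_equal(twice, once, tolerance = 1e-10)
})

test_that("MSC collapses gain/offset-corrupted copies of a common shape", {
  set.seed(4)
  shape <- exp(-(seq(-3, 3, length.out = 80))^2) + 0.3
  gains <- runif(6, 0.7, 1.3)
  offs <- runif(6, -0.2, 0.2)
  X <- outer(gains, shape) + offs
  # known reference: exact inversion
  rec <- msc(X, reference = shape)$spectra
  expect_equal(rec, matrix(shape, 6, 80, byrow = TRUE), tolerance = 1e-10)
  # mean reference: rows collapse onto one spectrum
  rec2 <- msc(X)$spectra
  expect_lt(max(apply(rec2, 2, sd)), 1e-10)
})

test_that("MSC rejects a degenerate reference", {
  expect_error(msc(matrix(rnorm(20), 4), reference = rep(1, 5)),
               "zero variance")
})

test_that("SNV centers and scales each spectrum", {
  expect_equal(as.numeric(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  set.seed(5)
  X <- matrix(rnorm(60), 6)
  out <- snv(X)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
  # affine invariance for positive gain
  expect_equal(snv(3.2 * X + 7), out, tolerance = 1e-12)
  Xc <- X; Xc[2, ] <- 4
  expect_error(snv(Xc), "row 2")
})

test_that("finite differences are exact for quadratics on interior channels", {
  M <- matrix(c(1, 4, 9, 16), 1, dimnames = list(NULL, 1:4))  # f = t^2, h = 1
  d1 <- spectral_derivative(M, 1)
  expect_equal(as.numeric(d1)[2:3], c(4, 6))
  d2 <- spectral_derivative(M, 2)
  expect_equal(as.numeric(d2)[2:3], c(2, 2))
  expect_equal(as.numeric(d2)[c(1, 4)], c(2, 2))  # endpoint copies
  const <- matrix(5, 1, 6, dimnames = list(NULL, seq(0, 50, 10)))
  expect_true(all(spectral_derivative(const, 1) == 0))
  bad <- matrix(1:4, 1, dimnames = list(NULL, c(1, 2, 4, 8)))
  expect_error(spectral_derivative(bad, 1), "not uniform")
})

test_that("normalizations transform columns as specified", {
  mm <- fit_normalizer(matrix(c(0, 5, 10), 3, 1), "minmax")
  expect_equal(as.numeric(apply_normalizer(matrix(c(0, 5, 10), 3, 1), mm)),
               c(-1, 0, 1))
  # value outside the calibration range extrapolates without clipping
  expect_equal(as.numeric(apply_normalizer(matrix(15, 1, 1), mm)), 2)

  # pareto divides the centered value by sqrt(sd)
  X <- matrix(c(-2, 2, 6), 3, 1)
  pa <- fit_normalizer(X, "pareto")
  sdX <- sd(X[, 1])
  expect_equal(as.numeric(apply_normalizer(matrix(6, 1, 1), pa)),
               (6 - 2) / sqrt(sdX))

  ac <- fit_normalizer(X, "autoscale")
  expect_equal(as.numeric(apply_normalizer(X, ac)), (X[, 1] - 2) / sdX)
  expect_error(fit_normalizer(matrix(1, 3, 1), "autoscale"), "zero SD")
  expect_error(fit_normalizer(matrix(c(-1, 0, 1), 3, 1), "poisson"),
               "non-positive mean")
  po <- fit_normalizer(matrix(c(1, 4), 2, 1), "poisson")
  expect_equal(as.numeric(apply_normalizer(matrix(c(1, 4), 2, 1), po)),
               c(1, 4) / sqrt(2.5))
  mc <- fit_normalizer(X, "mean_center")
  expect_equal(colMeans(apply_normalizer(X, mc)), 0)
  expect_error(fit_normalizer(matrix(2, 3, 1), "minmax"), "constant")
})

test_that("normalization parameters depend only on the calibration rows", {
  set.seed(7)
  cal <- matrix(rnorm(50), 10)
  pred_a <- matrix(rnorm(25), 5)
  perm <- c(3, 1, 5, 2, 4)
  for (m in c("mean_center", "autoscale", "pareto", "minmax")) {
    fit <- fit_normalizer(cal, m)
    refit <- fit_normalizer(cal, m)  # prediction rows never enter the fit
    expect_identical(fit$params, refit$params)
    # applying to permuted prediction rows just permutes the outputs
    expect_equal(apply_normalizer(pred_a[perm, ], fit),
                 apply_normalizer(pred_a, fit)[perm, ],
                 tolerance = 1e-12)
  }
})
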