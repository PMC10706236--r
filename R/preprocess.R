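# Accept a spectra_set or plain matrix; return list(mat, rebuild function).
as_spectra_matrix <- function(x) {
  if (inherits(x, "spectra_set")) {
    list(mat = x$absorbance, wn = x$wavenumbers,
         rebuild = function(m, wn = x$wavenumbers) spectra_with(x, m, wn))
  } else {
    m <- as.matrix(x)
    wn <- suppressWarnings(as.numeric(colnames(m)))
    if (length(wn) != ncol(m) || anyNA(wn)) wn <- seq_len(ncol(m))
    list(mat = m, wn = wn,
         rebuild = function(m2, wn = NULL) m2)
  }
}

#' Cubic smoothing-spline noise removal
#'
#' Smooths every spectrum over the wavenumber axis with a cubic smoothing
#' spline. The smoothing parameter `p` follows the classical penalized
#' least-squares trade-off
#' \deqn{p \sum_i (y_i - f(x_i))^2 + (1 - p) \int f''(x)^2 dx}
#' with `x` in original wavenumber units (the convention of MATLAB's
#' `csaps`): `p = 1` reproduces the data at the channels (natural-spline
#' interpolation) and `p -> 0` approaches the least-squares straight line.
#' Internally the fit delegates to [stats::smooth.spline()] with
#' `lambda = (1 - p) / (p * r^3)` where `r` is the wavenumber range (the
#' factor `r^3` converts the roughness integral to the unit interval that
#' `smooth.spline` works on).
#'
#' @param spectra A [spectra_set()] or numeric matrix with wavenumber
#'   column names.
#' @param p Smoothing parameter in `(0, 1]` (default 0.01).
#' @return Object of the same type as `spectra`.
#' @export
smooth_spectra <- function(spectra, p = 0.01) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stop("smoothing parameter p must lie in (0, 1]", call. = FALSE)
  }
  sm <- as_spectra_matrix(spectra)
  wn <- sm$wn
  if (length(wn) < 4) stop("smoothing needs at least 4 channels", call. = FALSE)
  if (p == 1) return(spectra)  # interpolation at the channels: identity
  r <- diff(range(wn))
  lambda <- (1 - p) / (p * r^3)
  out <- t(apply(sm$mat, 1, function(y) {
    smooth.spline(wn, y, lambda = lambda, all.knots = TRUE,
                  keep.data = FALSE, cv = NA)$y
  }))
  sm$rebuild(out)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares
#' (`row = a + b * reference`) and returns `(row - a) / b`, removing the
#' additive offset and multiplicative gain that light scatter imposes. When
#' no reference is supplied the mean spectrum of the input rows is used;
#' the reference actually used is returned so it can be reapplied unchanged
#' to prediction data.
#'
#' @param spectra A [spectra_set()] or matrix.
#' @param reference Optional reference spectrum (numeric vector).
#' @return List with elements `spectra` (corrected, same type as input) and
#'   `reference`.
#' @export
msc <- function(spectra, reference = NULL) {
  sm <- as_spectra_matrix(spectra)
  X <- sm$mat
  if (is.null(reference)) {
    if (nrow(X) < 2) {
      stop("msc needs at least 2 spectra to form a mean reference",
           call. = FALSE)
    }
    reference <- colMeans(X)
  }
  if (length(reference) != ncol(X)) {
    stop("reference length must equal the channel count", call. = FALSE)
  }
  vref <- sum((reference - mean(reference))^2)
  if (vref <= 0) stop("MSC reference spectrum has zero variance", call. = FALSE)
  rc <- reference - mean(reference)
  out <- t(apply(X, 1, function(row) {
    b <- sum((row - mean(row)) * rc) / vref
    if (abs(b) < 1e-12) {
      stop("MSC gain estimate is zero for a spectrum; cannot correct",
           call. = FALSE)
    }
    a <- mean(row) - b * mean(reference)
    (row - a) / b
  }))
  list(spectra = sm$rebuild(out), reference = reference)
}

#' Standard normal variate transform
#'
#' Centers every spectrum to mean 0 and scales it to unit standard
#' deviation (`n - 1` divisor), removing per-spectrum offset and gain.
#'
#' @param spectra A [spectra_set()] or matrix.
#' @return Same type as input.
#' @export
snv <- function(spectra) {
  sm <- as_spectra_matrix(spectra)
  X <- sm$mat
  sds <- apply(X, 1, sd)
  if (any(sds <= 0)) {
    stop(sprintf("constant spectrum (zero SD) at row %d; SNV undefined",
                 which(sds <= 0)[1]), call. = FALSE)
  }
  out <- (X - rowMeans(X)) / sds
  sm$rebuild(out)
}

#' Finite-difference spectral derivatives
#'
#' First or second derivative along the wavenumber axis by central finite
#' differences on the uniform grid: interior channels use
#' `(x[i+1] - x[i-1]) / (2h)` and `(x[i+1] - 2 x[i] + x[i-1]) / h^2`;
#' endpoints use the one-sided first-order difference (order 1) or copy the
#' adjacent interior value (order 2), keeping the channel count unchanged.
#'
#' @param spectra A [spectra_set()] or matrix.
#' @param order 1 or 2.
#' @param tol Relative tolerance for grid uniformity.
#' @return Same type as input (units per cm^-1 or per cm^-2).
#' @export
spectral_derivative <- function(spectra, order = 1, tol = 1e-8) {
  if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
  sm <- as_spectra_matrix(spectra)
  wn <- sm$wn
  m <- ncol(sm$mat)
  if (m < 3) stop("derivatives need at least 3 channels", call. = FALSE)
  h <- diff(wn)
  if (max(abs(h - h[1])) > tol * abs(h[1])) {
    stop("wavenumber grid is not uniform; finite differences undefined",
         call. = FALSE)
  }
  h <- h[1]
  X <- sm$mat
  i <- 2:(m - 1)
  out <- X * 0
  if (order == 1) {
    out[, i] <- (X[, i + 1] - X[, i - 1]) / (2 * h)
    out[, 1] <- (X[, 2] - X[, 1]) / h
    out[, m] <- (X[, m] - X[, m - 1]) / h
  } else {
    out[, i] <- (X[, i + 1] - 2 * X[, i] + X[, i - 1]) / h^2
    out[, 1] <- out[, 2]
    out[, m] <- out[, m - 1]
  }
  sm$rebuild(out)
}

#' Fit a column normalization on calibration data
#'
#' Column-wise transforms applied after pre-treatment, fitted on calibration
#' rows only and reapplied unchanged to prediction rows:
#' `mean_center` subtracts the column mean; `autoscale` divides the centered
#' column by its SD; `pareto` divides by the square root of the SD;
#' `poisson` divides raw values by the square root of the column mean
#' (requires positive means); `minmax` maps the calibration `[min, max]`
#' affinely to `[-1, +1]` (values outside the calibration range map outside
#' `[-1, 1]`, without clipping).
#'
#' @param X Numeric matrix (calibration rows).
#' @param method One of `"mean_center"`, `"autoscale"`, `"pareto"`,
#'   `"poisson"`, `"minmax"`.
#' @return An object of class `normalizer` holding the fitted per-column
#'   statistics.
#' @export
fit_normalizer <- function(X, method = c("mean_center", "autoscale", "pareto",
                                         "poisson", "minmax")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  mu <- colMeans(X)
  params <- switch(method,
    mean_center = list(mu = mu),
    autoscale = , pareto = {
      sigma <- apply(X, 2, sd)
      if (any(sigma <= 0)) {
        stop(sprintf("column %d has zero SD; %s undefined",
                     which(sigma <= 0)[1], method), call. = FALSE)
      }
      list(mu = mu, sigma = sigma)
    },
    poisson = {
      if (any(mu <= 0)) {
        stop(sprintf("column %d has non-positive mean; poisson scaling undefined",
                     which(mu <= 0)[1]), call. = FALSE)
      }
      list(mu = mu)
    },
    minmax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      if (any(hi - lo <= 0)) {
        stop(sprintf("column %d is constant; minmax scaling undefined",
                     which(hi - lo <= 0)[1]), call. = FALSE)
      }
      list(lo = lo, hi = hi)
    })
  structure(list(method = method, params = params, n_channels = ncol(X)),
            class = "normalizer")
}

#' Apply a fitted normalization
#' @param X Numeric matrix with the training channel count.
#' @param normalizer A fitted `normalizer` from [fit_normalizer()].
#' @return Transformed matrix.
#' @export
apply_normalizer <- function(X, normalizer) {
  stopifnot(inherits(normalizer, "normalizer"))
  X <- as.matrix(X)
  if (ncol(X) != normalizer$n_channels) {
    stop(sprintf("expected %d channels, got %d",
                 normalizer$n_channels, ncol(X)), call. = FALSE)
  }
  p <- normalizer$params
  switch(normalizer$method,
    mean_center = sweep(X, 2, p$mu),
    autoscale = sweep(sweep(X, 2, p$mu), 2, p$sigma, "/"),
    pareto = sweep(sweep(X, 2, p$mu), 2, sqrt(p$sigma), "/"),
    poisson = sweep(X, 2, sqrt(p$mu), "/"),
    minmax = sweep(sweep(X, 2, p$lo), 2, (p$hi - p$lo) / 2, "/") - 1)
}

# Pre-treatment dispatcher used by the pipeline. Row-local methods ignore
# `msc_reference`; MSC fits (or reuses) its reference. Returns the treated
# object plus the state needed to reapply the identical transform.
apply_pretreatment <- function(spectra, method = c("MSC", "SNV", "D1", "D2"),
                               msc_reference = NULL) {
  method <- match.arg(method)
  switch(method,
    MSC = {
      res <- msc(spectra, reference = msc_reference)
      list(spectra = res$spectra, msc_reference = res$reference)
    },
    SNV = list(spectra = snv(spectra), msc_reference = NULL),
    D1 = list(spectra = spectral_derivative(spectra, 1), msc_reference = NULL),
    D2 = list(spectra = spectral_derivative(spectra, 2), msc_reference = NULL))
}
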