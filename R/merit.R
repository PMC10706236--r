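#' Root-mean-square error
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return RMSE in the units of the observations.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` about the mean of the observations (not the squared
#' correlation; it can be negative for models worse than the mean).
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Unitless value <= 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' Percentual relative standard deviation of prediction
#'
#' `100 * RMSE / mean(observed)` — the prediction error as a percentage of
#' the mean reference magnitude. This denominator convention is declared in
#' every merit report.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Percent.
#' @export
rsd_percent <- function(observed, predicted) {
  m <- mean(observed)
  if (m == 0) stop("mean of observed values is zero; RSD undefined",
                   call. = FALSE)
  100 * rmse(observed, predicted) / m
}

#' Elliptical joint confidence region test for trueness
#'
#' Regresses predicted on observed by OLS and builds the elliptical joint
#' confidence region of (intercept, slope) from the F distribution with
#' (2, n - 2) degrees of freedom. The model is declared accurate when the
#' region contains the ideal point (0, 1).
#'
#' @param observed,predicted Numeric vectors, `n >= 3`.
#' @param alpha Significance level (default 0.05 for a 95\% region).
#' @return List of class `ejcr`: `contains_ideal`, `statistic` (the scaled
#'   quadratic form at (0, 1)), `critical` (F quantile), `intercept`,
#'   `slope`, `sigma2`, `xtx`, `alpha`, `degenerate`.
#' @export
ejcr_test <- function(observed, predicted, alpha = 0.05) {
  n <- length(observed)
  if (n < 3) stop("EJCR needs at least 3 points", call. = FALSE)
  if (length(predicted) != n) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  Z <- cbind(1, observed)
  xtx <- crossprod(Z)
  b <- drop(solve(xtx, crossprod(Z, predicted)))
  res <- predicted - drop(Z %*% b)
  s2 <- sum(res^2) / (n - 2)
  crit <- qf(1 - alpha, 2, n - 2)
  if (s2 < 1e-20) {
    return(structure(list(contains_ideal = TRUE, statistic = 0,
                          critical = crit, intercept = b[1], slope = b[2],
                          sigma2 = s2, xtx = xtx, alpha = alpha,
                          degenerate = TRUE), class = "ejcr"))
  }
  delta <- b - c(0, 1)
  stat <- drop(t(delta) %*% xtx %*% delta) / (2 * s2)
  structure(list(contains_ideal = stat <= crit, statistic = stat,
                 critical = crit, intercept = b[1], slope = b[2],
                 sigma2 = s2, xtx = xtx, alpha = alpha, degenerate = FALSE),
            class = "ejcr")
}

#' @export
print.ejcr <- function(x, ...) {
  cat(sprintf("<ejcr> intercept %.4f, slope %.4f; F-statistic %.3f vs critical %.3f (alpha %.2f): ideal point (0,1) %s\n",
              x$intercept, x$slope, x$statistic, x$critical, x$alpha,
              if (x$contains_ideal) "inside" else "outside"))
  invisible(x)
}

#' Durbin-Watson test for first-order residual autocorrelation
#'
#' `DW = sum(diff(e)^2) / sum(e^2)`, in `[0, 4]` with 2 meaning no
#' autocorrelation. The two-sided probability uses the large-sample normal
#' approximation to the null distribution for i.i.d. residuals,
#' `DW ~ N(2, 4/n)`; a non-significant probability (p > 0.05) indicates no
#' evidence of serial structure in the residuals.
#'
#' @param residuals Numeric vector, `n >= 3`, not all zero.
#' @return List with `statistic` and `p_value`.
#' @export
durbin_watson <- function(residuals) {
  n <- length(residuals)
  if (n < 3) stop("Durbin-Watson needs at least 3 residuals", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom <= 0) stop("all residuals are zero; DW undefined", call. = FALSE)
  d <- sum(diff(residuals)^2) / denom
  p <- 2 * pnorm(-abs(d - 2) / (2 / sqrt(n)))
  list(statistic = d, p_value = p)
}

#' Assemble the figures of merit of a fitted calibration
#'
#' One row of the per-attribute report: calibration and prediction RMSE and
#' R-squared, prediction RSD\%, the EJCR trueness verdict and the
#' Durbin-Watson statistic/probability of the prediction residuals (taken
#' in dataset row order).
#'
#' @param model Fitted model with a `predict` method operating on rows of
#'   `X`.
#' @param X Full predictor matrix (all samples, model-ready).
#' @param y Full response vector.
#' @param split A `split_result` from [spxy()].
#' @param attribute Attribute name carried into the report.
#' @param alpha EJCR significance level.
#' @return An object of class `merit_report` (a one-row data.frame plus an
#'   `ejcr` attribute), columns: `attribute`, `rmsec`, `r2_cal`, `rmsep`,
#'   `r2_pred`, `rsd_pred_pct`, `ejcr_contains_ideal`, `dw_statistic`,
#'   `dw_probability`, `rsd_convention`.
#' @export
merit_report <- function(model, X, y, split, attribute = "", alpha = 0.05) {
  stopifnot(inherits(split, "split_result"))
  cal <- split$calibration_idx; prd <- split$prediction_idx
  yc_hat <- predict(model, X[cal, , drop = FALSE])
  yp_hat <- predict(model, X[prd, , drop = FALSE])
  ej <- ejcr_test(y[prd], yp_hat, alpha = alpha)
  dw <- durbin_watson(y[prd] - yp_hat)
  out <- data.frame(
    attribute = attribute,
    rmsec = rmse(y[cal], yc_hat),
    r2_cal = r_squared(y[cal], yc_hat),
    rmsep = rmse(y[prd], yp_hat),
    r2_pred = r_squared(y[prd], yp_hat),
    rsd_pred_pct = rsd_percent(y[prd], yp_hat),
    ejcr_contains_ideal = ej$contains_ideal,
    dw_statistic = dw$statistic,
    dw_probability = dw$p_value,
    rsd_convention = "100*RMSEP/mean(observed)",
    stringsAsFactors = FALSE)
  attr(out, "ejcr") <- ej
  class(out) <- c("merit_report", "data.frame")
  out
}
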