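#' Specify a support-vector regression model
#'
#' Validates that exactly the parameters licensed for the chosen SVR type
#' and kernel are supplied: `epsilon` only for \eqn{\epsilon}-SVR, `nu` only
#' for \eqn{\nu}-SVR, `gamma` for every kernel except the linear one,
#' `coef0` only for polynomial and sigmoid kernels, and `degree`
#' (integer 2--5) only for the polynomial kernel.
#'
#' @param svr_type `"epsilon"` or `"nu"`.
#' @param kernel `"linear"`, `"polynomial"`, `"radial_base"` or `"sigmoid"`.
#' @param C Penalty, > 0.
#' @param epsilon Insensitive-tube width, >= 0 (epsilon type only).
#' @param nu In (0, 1] (nu type only).
#' @param gamma Kernel scale, > 0 (all kernels except linear).
#' @param coef0 Intercept term (polynomial and sigmoid kernels).
#' @param degree Integer in 2--5 (polynomial kernel).
#' @return An object of class `svr_spec`.
#' @export
svr_spec <- function(svr_type = c("epsilon", "nu"),
                     kernel = c("radial_base", "linear", "polynomial", "sigmoid"),
                     C, epsilon = NULL, nu = NULL, gamma = NULL,
                     coef0 = NULL, degree = NULL) {
  svr_type <- match.arg(svr_type)
  kernel <- match.arg(kernel)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (svr_type == "epsilon") {
    if (is.null(epsilon) || epsilon < 0) {
      stop("epsilon-SVR requires epsilon >= 0", call. = FALSE)
    }
    if (!is.null(nu)) stop("nu is licensed only for nu-SVR", call. = FALSE)
  } else {
    if (is.null(nu) || nu <= 0 || nu > 1) {
      stop("nu-SVR requires nu in (0, 1]", call. = FALSE)
    }
    if (!is.null(epsilon)) {
      stop("epsilon is licensed only for epsilon-SVR", call. = FALSE)
    }
  }
  if (kernel == "linear") {
    if (!is.null(gamma)) {
      stop("gamma is licensed for every kernel except the linear one",
           call. = FALSE)
    }
  } else {
    if (is.null(gamma) || gamma <= 0) {
      stop(sprintf("kernel '%s' requires gamma > 0", kernel), call. = FALSE)
    }
  }
  if (kernel %in% c("polynomial", "sigmoid")) {
    if (is.null(coef0)) coef0 <- 0
  } else if (!is.null(coef0)) {
    stop("coef0 (intercept) is licensed only for polynomial and sigmoid kernels",
         call. = FALSE)
  }
  if (kernel == "polynomial") {
    if (is.null(degree) || degree != round(degree) || degree < 2 || degree > 5) {
      stop("polynomial kernel requires an integer degree in 2..5", call. = FALSE)
    }
    degree <- as.integer(degree)
  } else if (!is.null(degree)) {
    stop("degree is licensed only for the polynomial kernel", call. = FALSE)
  }
  structure(list(svr_type = svr_type, kernel = kernel, C = C,
                 epsilon = epsilon, nu = nu, gamma = gamma,
                 coef0 = coef0, degree = degree),
            class = "svr_spec")
}

#' @export
print.svr_spec <- function(x, ...) {
  pars <- c(C = x$C, epsilon = x$epsilon, nu = x$nu, gamma = x$gamma,
            coef0 = x$coef0, degree = x$degree)
  cat(sprintf("<svr_spec> %s-SVR, %s kernel: %s\n", x$svr_type, x$kernel,
              paste(names(pars), signif(pars, 4), sep = "=", collapse = ", ")))
  invisible(x)
}

e1071_kernel <- c(linear = "linear", polynomial = "polynomial",
                  radial_base = "radial", sigmoid = "sigmoid")

#' Fit a support-vector regression model
#'
#' Solves the standard \eqn{\epsilon}-/\eqn{\nu}-SVR dual with the specified
#' kernel through the libsvm solver (package \pkg{e1071}), without internal
#' rescaling of X or y. The fit is deterministic for fixed inputs.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Numeric response vector.
#' @param spec An [svr_spec()].
#' @return An object of class `svr_model`.
#' @export
fit_svr <- function(X, y, spec) {
  stopifnot(inherits(spec, "svr_spec"))
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  args <- list(x = X, y = y, scale = FALSE,
               type = if (spec$svr_type == "epsilon") "eps-regression" else "nu-regression",
               kernel = e1071_kernel[[spec$kernel]],
               cost = spec$C, fitted = FALSE, na.action = stats::na.fail)
  if (!is.null(spec$epsilon)) args$epsilon <- spec$epsilon
  if (!is.null(spec$nu)) args$nu <- spec$nu
  if (!is.null(spec$gamma)) args$gamma <- spec$gamma
  if (!is.null(spec$coef0)) args$coef0 <- spec$coef0
  if (!is.null(spec$degree)) args$degree <- spec$degree
  fit <- do.call(e1071::svm, args)
  structure(list(spec = spec, fit = fit, n_channels = ncol(X)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_channels) {
    stop(sprintf("expected %d channels, got %d",
                 object$n_channels, ncol(newdata)), call. = FALSE)
  }
  if (object$fit$tot.nSV == 0) {
    # epsilon tube wide enough to cover all training targets: the dual
    # solution is empty and the regression function is the constant -rho
    return(rep(-object$fit$rho, nrow(newdata)))
  }
  as.numeric(predict(object$fit, newdata))
}

#' Fit a PLS1 regression baseline (NIPALS)
#'
#' Univariate partial least squares by the NIPALS algorithm on centered X
#' and y. When `n_components` is omitted it is chosen to minimize the
#' 5-fold cross-validated RMSE over `1..max_components`.
#'
#' @param X Numeric matrix.
#' @param y Numeric response vector.
#' @param n_components Number of latent variables,
#'   `1 <= n_components <= min(nrow(X) - 1, ncol(X))`; `NULL` to select by
#'   RMSECV.
#' @param max_components Search ceiling for automatic selection.
#' @param cv_seed Seed for the selection folds.
#' @return An object of class `pls_model`.
#' @export
fit_pls <- function(X, y, n_components = NULL, max_components = 10,
                    cv_seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ub <- min(n - 1L, p)
  if (is.null(n_components)) {
    amax <- min(max_components, ub)
    cvs <- vapply(seq_len(amax), function(a) {
      kfold_rmsecv(X, y, pls_spec(a), k = min(5, n), seed = cv_seed)
    }, numeric(1))
    n_components <- which.min(cvs)
  }
  if (n_components < 1 || n_components > ub) {
    stop(sprintf("n_components must lie in [1, %d], got %g", ub, n_components),
         call. = FALSE)
  }
  mx <- colMeans(X); my <- mean(y)
  X0 <- sweep(X, 2, mx); y0 <- y - my
  A <- as.integer(n_components)
  W <- P <- matrix(0, p, A); q <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(X0, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X residual orthogonal to y: nothing left
    w <- w / nw
    t_ <- drop(X0 %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    P[, a] <- drop(crossprod(X0, t_)) / tt
    q[a] <- sum(y0 * t_) / tt
    W[, a] <- w
    X0 <- X0 - tcrossprod(t_, P[, a])
    y0 <- y0 - q[a] * t_
    a_eff <- a
  }
  if (a_eff == 0L) stop("y is uncorrelated with X; PLS undefined", call. = FALSE)
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  q <- q[seq_len(a_eff)]
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(n_components = a_eff, coef = drop(B),
                 intercept = my - sum(mx * drop(B)),
                 x_mean = mx, y_mean = my, n_channels = p),
            class = "pls_model")
}

# Lightweight model-spec marker so the CV driver can fit PLS baselines.
#' Specify a PLS baseline for cross-validation
#' @param n_components Number of latent variables.
#' @return Object of class `pls_spec`.
#' @export
pls_spec <- function(n_components) {
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  structure(list(n_components = as.integer(n_components)), class = "pls_spec")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_channels) {
    stop(sprintf("expected %d channels, got %d",
                 object$n_channels, ncol(newdata)), call. = FALSE)
  }
  drop(newdata %*% object$coef) + object$intercept
}

fit_model_spec <- function(X, y, spec) {
  if (inherits(spec, "svr_spec")) {
    fit_svr(X, y, spec)
  } else if (inherits(spec, "pls_spec")) {
    fit_pls(X, y, n_components = min(spec$n_components,
                                     nrow(as.matrix(X)) - 1L,
                                     ncol(as.matrix(X))))
  } else {
    stop("spec must be an svr_spec or pls_spec", call. = FALSE)
  }
}

#' Deterministic k-fold assignment
#'
#' Indices are shuffled once under the seed, then cut into contiguous
#' blocks whose sizes differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds (`k <= n`).
#' @param seed Integer seed (or `NULL` for the current RNG state).
#' @return List of `k` integer index vectors.
#' @export
make_folds <- function(n, k, seed = NULL) {
  if (k > n) stop(sprintf("k = %d exceeds n = %d", k, n), call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}

#' k-fold cross-validated RMSE
#'
#' RMSECV with the pooled convention: all held-out squared errors are
#' accumulated and `sqrt(sum(se) / n)` is returned (not the mean of
#' per-fold RMSEs; set `pooled = FALSE` for that variant). Fold assignment
#' is deterministic for a fixed seed, so the value is a valid optimizer
#' objective.
#'
#' @param X Numeric matrix.
#' @param y Numeric response vector.
#' @param spec An [svr_spec()] or [pls_spec()].
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment (ignored when `folds` is given).
#' @param folds Optional precomputed folds from [make_folds()].
#' @param pooled Pool squared errors across folds (default `TRUE`).
#' @return RMSECV in the units of `y`.
#' @export
kfold_rmsecv <- function(X, y, spec, k = 5, seed = NULL, folds = NULL,
                         pooled = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  if (pooled) {
    sse <- 0
    for (f in folds) {
      m <- fit_model_spec(X[-f, , drop = FALSE], y[-f], spec)
      sse <- sse + sum((predict(m, X[f, , drop = FALSE]) - y[f])^2)
    }
    sqrt(sse / n)
  } else {
    mean(vapply(folds, function(f) {
      m <- fit_model_spec(X[-f, , drop = FALSE], y[-f], spec)
      sqrt(mean((predict(m, X[f, , drop = FALSE]) - y[f])^2))
    }, numeric(1)))
  }
}
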