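#' Configuration for the hybrid PSO + pattern-search optimizer
#'
#' Global-best particle swarm with inertia/cognitive/social coefficients,
#' velocity clamping and boundary reflection, followed by a coordinate
#' pattern-search polish of the swarm optimum. Defaults use the standard
#' constriction-equivalent coefficients (0.729, 1.49445, 1.49445).
#'
#' @param swarm_size Number of particles (>= 2).
#' @param max_iterations Swarm iterations.
#' @param inertia,cognitive,social Velocity update coefficients (>= 0).
#' @param patience Stop after this many iterations without improvement of
#'   the global best.
#' @param ps_step Initial pattern-search step as a fraction of each
#'   parameter's (possibly log-scaled) range.
#' @param ps_contraction Step contraction factor in (0, 1).
#' @param ps_tolerance Terminate polling when the step fraction falls below
#'   this value.
#' @param seed Integer seed; fixes the whole optimization trajectory.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 20L, max_iterations = 50L,
                       inertia = 0.729, cognitive = 1.49445, social = 1.49445,
                       patience = 10L, ps_step = 0.1, ps_contraction = 0.5,
                       ps_tolerance = 1e-4, seed = NULL) {
  if (swarm_size < 2) stop("swarm_size must be >= 2", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (any(c(inertia, cognitive, social) < 0)) {
    stop("PSO coefficients must be >= 0", call. = FALSE)
  }
  if (ps_contraction <= 0 || ps_contraction >= 1) {
    stop("ps_contraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iterations = as.integer(max_iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 patience = as.integer(patience), ps_step = ps_step,
                 ps_contraction = ps_contraction,
                 ps_tolerance = ps_tolerance,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pso_config")
}

#' Preset optimizer budgets
#'
#' `"ci"` is a desk-scale budget sized so that a ten-attribute tuning run
#' completes in minutes; `"paper"` is a thorough budget for final models.
#'
#' @param scale `"ci"` or `"paper"`.
#' @param seed Optional seed forwarded to [pso_config()].
#' @return A [pso_config()].
#' @export
pso_preset <- function(scale = c("ci", "paper"), seed = NULL) {
  scale <- match.arg(scale)
  switch(scale,
         ci = pso_config(swarm_size = 10L, max_iterations = 20L,
                         patience = 6L, ps_tolerance = 1e-3, seed = seed),
         paper = pso_config(swarm_size = 20L, max_iterations = 50L,
                            patience = 10L, seed = seed))
}

# Bounds descriptor: data.frame(name, lower, upper, log, integer).
param_bounds <- function(name, lower, upper, log = FALSE, integer = FALSE) {
  data.frame(name = name, lower = lower, upper = upper, log = log,
             integer = integer, stringsAsFactors = FALSE)
}

validate_bounds <- function(bounds) {
  stopifnot(is.data.frame(bounds),
            all(c("name", "lower", "upper", "log") %in% names(bounds)))
  if (!"integer" %in% names(bounds)) bounds$integer <- FALSE
  if (any(bounds$lower >= bounds$upper)) {
    stop("each bound must satisfy lower < upper", call. = FALSE)
  }
  if (any(bounds$log & bounds$lower <= 0)) {
    stop("log-scaled parameters need positive lower bounds", call. = FALSE)
  }
  bounds
}

to_search <- function(x, bounds) ifelse(bounds$log, log10(x), x)
from_search <- function(s, bounds) {
  x <- ifelse(bounds$log, 10^s, s)
  setNames(x, bounds$name)
}

#' Minimize an objective with particle swarm + pattern search
#'
#' Standard global-best PSO on the bounded box: velocities are clamped to
#' half the box range, particles leaving the box are reflected back and
#' their velocity reversed, and log-flagged parameters are searched in
#' log10 space. After the swarm phase (or early stop on `patience`
#' stagnant iterations) the global best is polished by coordinate pattern
#' search. The run is deterministic for a fixed `config$seed`.
#'
#' @param objective Function taking a named parameter vector (original
#'   scale), returning a finite scalar to minimize.
#' @param bounds Data frame with columns `name`, `lower`, `upper`, `log`
#'   (and optionally `integer`), one row per parameter.
#' @param config A [pso_config()].
#' @return An object of class `tuning_result`: `best_par` (named vector),
#'   `best_value`, `trajectory` (best objective after each iteration,
#'   non-increasing, ending with the pattern-search value), `evaluations`.
#' @export
pso_minimize <- function(objective, bounds, config = pso_config()) {
  bounds <- validate_bounds(bounds)
  d <- nrow(bounds)
  lo <- to_search(bounds$lower, bounds)
  hi <- to_search(bounds$upper, bounds)
  rng <- hi - lo
  vmax <- 0.5 * rng
  evals <- 0L
  eval_s <- function(s) {
    evals <<- evals + 1L
    v <- objective(from_search(pmin(hi, pmax(lo, s)), bounds))
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) Inf else v
  }
  with_local_seed(config$seed, {
    np <- config$swarm_size
    Xs <- matrix(runif(np * d, lo, hi), nrow = np, byrow = TRUE)
    Vs <- matrix(runif(np * d, -vmax, vmax), nrow = np, byrow = TRUE) * 0.1
    fx <- apply(Xs, 1, eval_s)
    if (all(!is.finite(fx))) {
      stop("objective is non-finite at every initial particle", call. = FALSE)
    }
    Pb <- Xs; fpb <- fx
    g <- which.min(fpb)
    gb <- Pb[g, ]; fgb <- fpb[g]
    trajectory <- numeric(0)
    stagnant <- 0L
    for (iter in seq_len(config$max_iterations)) {
      r1 <- matrix(runif(np * d), np)
      r2 <- matrix(runif(np * d), np)
      Vs <- config$inertia * Vs +
        config$cognitive * r1 * (Pb - Xs) +
        config$social * r2 * sweep(Xs, 2, gb, function(x, g) g - x)
      Vs <- pmin(pmax(Vs, matrix(-vmax, np, d, byrow = TRUE)),
                 matrix(vmax, np, d, byrow = TRUE))
      Xs <- Xs + Vs
      for (j in seq_len(d)) {
        under <- Xs[, j] < lo[j]; over <- Xs[, j] > hi[j]
        Xs[under, j] <- pmin(hi[j], 2 * lo[j] - Xs[under, j])
        Xs[over, j] <- pmax(lo[j], 2 * hi[j] - Xs[over, j])
        Vs[under | over, j] <- -Vs[under | over, j]
      }
      fx <- apply(Xs, 1, eval_s)
      improved <- fx < fpb
      Pb[improved, ] <- Xs[improved, , drop = FALSE]
      fpb[improved] <- fx[improved]
      g <- which.min(fpb)
      if (fpb[g] < fgb) {
        fgb <- fpb[g]; gb <- Pb[g, ]; stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      trajectory <- c(trajectory, fgb)
      if (stagnant >= config$patience) break
    }
    ps <- pattern_search_refine(objective, from_search(gb, bounds), bounds,
                                config = config)
    evals <- evals + ps$evaluations
    if (ps$value <= fgb) {
      gb_par <- ps$par; fgb <- ps$value
    } else {
      gb_par <- from_search(gb, bounds)  # contract guarantees this cannot occur
    }
    trajectory <- c(trajectory, fgb)
    structure(list(best_par = gb_par, best_value = fgb,
                   trajectory = trajectory, evaluations = evals,
                   bounds = bounds),
              class = "tuning_result")
  })
}

#' Coordinate pattern-search refinement
#'
#' Polls both directions of every coordinate at the current step (a
#' fraction of each parameter's range, log-scaled where flagged), moves to
#' the best improving neighbor, and contracts the step when no poll
#' improves, until the step fraction falls below `ps_tolerance`. Never
#' returns a point worse than the start.
#'
#' @param objective As in [pso_minimize()].
#' @param x0 Named start vector (original scale), inside bounds.
#' @param bounds As in [pso_minimize()].
#' @param config A [pso_config()] (step, contraction, tolerance are used).
#' @return List with `par`, `value`, `evaluations`.
#' @export
pattern_search_refine <- function(objective, x0, bounds,
                                  config = pso_config()) {
  bounds <- validate_bounds(bounds)
  lo <- to_search(bounds$lower, bounds)
  hi <- to_search(bounds$upper, bounds)
  rng <- hi - lo
  s <- pmin(hi, pmax(lo, to_search(unname(x0[bounds$name]), bounds)))
  evals <- 0L
  eval_s <- function(ss) {
    evals <<- evals + 1L
    v <- objective(from_search(ss, bounds))
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) Inf else v
  }
  fbest <- eval_s(s)
  step <- config$ps_step
  d <- length(s)
  while (step >= config$ps_tolerance) {
    improved <- FALSE
    for (j in seq_len(d)) {
      for (dir in c(1, -1)) {
        cand <- s
        cand[j] <- min(hi[j], max(lo[j], s[j] + dir * step * rng[j]))
        if (cand[j] == s[j]) next
        fc <- eval_s(cand)
        if (fc < fbest) {
          s <- cand; fbest <- fc; improved <- TRUE
        }
      }
    }
    if (!improved) step <- step * config$ps_contraction
  }
  list(par = from_search(s, bounds), value = fbest, evaluations = evals)
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> best objective %.6g after %d evaluations\n",
              x$best_value, x$evaluations))
  cat("  best parameters:",
      paste(names(x$best_par), signif(x$best_par, 4), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# Orthonormal row-space compression: Z = X V has the same Gram matrix and
# pairwise distances as X, so kernel methods give identical fits on it.
compress_rowspace <- function(X) {
  if (ncol(X) <= nrow(X)) return(X)
  sv <- svd(X, nu = 0)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  X %*% sv$v[, seq_len(r), drop = FALSE]
}

# Search box licensed by the (svr_type, kernel) combination.
svr_search_bounds <- function(svr_type, kernel) {
  b <- param_bounds("C", 1e-2, 1e2, log = TRUE)
  if (svr_type == "epsilon") {
    b <- rbind(b, param_bounds("epsilon", 1e-3, 1, log = TRUE))
  } else {
    b <- rbind(b, param_bounds("nu", 0.01, 0.99))
  }
  if (kernel != "linear") {
    b <- rbind(b, param_bounds("gamma", 1e-3, 1, log = TRUE))
  }
  if (kernel %in% c("polynomial", "sigmoid")) {
    b <- rbind(b, param_bounds("coef0", -1, 1))
  }
  if (kernel == "polynomial") {
    b <- rbind(b, param_bounds("degree", 2, 5, integer = TRUE))
  }
  b
}

par_to_svr_spec <- function(par, svr_type, kernel) {
  svr_spec(svr_type = svr_type, kernel = kernel,
           C = par[["C"]],
           epsilon = if ("epsilon" %in% names(par)) par[["epsilon"]] else NULL,
           nu = if ("nu" %in% names(par)) par[["nu"]] else NULL,
           gamma = if ("gamma" %in% names(par)) par[["gamma"]] else NULL,
           coef0 = if ("coef0" %in% names(par)) par[["coef0"]] else NULL,
           degree = if ("degree" %in% names(par)) round(par[["degree"]]) else NULL)
}

#' Tune SVR hyperparameters by PSO + pattern search
#'
#' The search box contains exactly the parameters licensed by the SVR type
#' and kernel (C always; epsilon or nu by type; gamma for all kernels but
#' the linear one; coef0 for polynomial/sigmoid; integer degree 2--5 for
#' polynomial, rounded at evaluation). The objective is the pooled 5-fold
#' cross-validated RMSE on fixed folds: every candidate is scored against
#' the identical fold assignment derived from `cv_seed`.
#'
#' @param X Calibration matrix.
#' @param y Calibration responses.
#' @param svr_type `"epsilon"` or `"nu"`.
#' @param kernel Kernel name.
#' @param config A [pso_config()].
#' @param cv_seed Seed fixing the cross-validation folds.
#' @param k Folds (default 5).
#' @param bounds Optional override of the default search box.
#' @return A `tuning_result` with the extra elements `best_spec` (an
#'   [svr_spec()]) and `best_rmsecv`.
#' @export
tune_svr <- function(X, y, svr_type = "epsilon", kernel = "radial_base",
                     config = pso_config(), cv_seed = 1L, k = 5,
                     bounds = NULL) {
  svr_type <- match.arg(svr_type, c("epsilon", "nu"))
  kernel <- match.arg(kernel, c("radial_base", "linear", "polynomial", "sigmoid"))
  bounds <- validate_bounds(bounds %||% svr_search_bounds(svr_type, kernel))
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), min(k, nrow(X)), cv_seed)
  # Every licensed kernel depends on X only through inner products or
  # Euclidean distances, both invariant under an orthonormal change of
  # basis of the row space. Projecting onto that basis (rank <= n) leaves
  # every CV objective value unchanged while removing the channel-count
  # overhead from each of the thousands of solver calls.
  Z <- compress_rowspace(X)
  objective <- function(par) {
    spec <- par_to_svr_spec(par, svr_type, kernel)
    kfold_rmsecv(Z, y, spec, folds = folds)
  }
  res <- pso_minimize(objective, bounds, config)
  res$best_spec <- par_to_svr_spec(res$best_par, svr_type, kernel)
  res$best_rmsecv <- res$best_value
  res
}
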