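# Kennard-Stone selection on a precomputed distance matrix. Tie-breaks are
# deterministic: the lexicographically lowest index (pair) wins.
ks_from_dist <- function(D, k) {
  n <- nrow(D)
  if (k < 2 || k > n) {
    stop(sprintf("k must lie in [2, %d], got %g", n, k), call. = FALSE)
  }
  # seed pair: maximal distance, lowest (i, j) on ties
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
  }
  if (bestd <= 0) {
    stop("all pairwise distances are zero; selection undefined", call. = FALSE)
  }
  selected <- best
  mind <- pmin(D[, best[1]], D[, best[2]])
  while (length(selected) < k) {
    mind[selected] <- -Inf
    cand <- which.max(mind)  # first (lowest-index) maximum
    selected <- c(selected, cand)
    mind <- pmin(mind, D[, cand])
  }
  as.integer(selected)
}

#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection: the first two picks are the pair of
#' samples at maximal Euclidean distance; every later pick maximizes its
#' minimum distance to the already selected set. Ties resolve to the lowest
#' index.
#'
#' @param X Numeric matrix, one row per sample.
#' @param k Number of samples to select (`2 <= k <= nrow(X)`).
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  ks_from_dist(as.matrix(stats::dist(X)), k)
}

#' SPXY calibration/prediction partitioning
#'
#' Joint X-Y variant of Kennard-Stone: pairwise Euclidean distances are
#' computed separately in instrument space (`X`) and response space (`y`),
#' each normalized by its maximum, and summed:
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`. Kennard-Stone selection on
#' the combined distance yields the calibration set; the remainder is the
#' prediction set. The calibration size is `round(fraction * n)` with
#' half-up rounding.
#'
#' @param X Numeric matrix, one row per sample.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param fraction Target calibration fraction (default 0.67).
#' @return An object of class `split_result`: list with
#'   `calibration_idx` (in selection order), `prediction_idx` (ascending)
#'   and `fraction`.
#' @export
spxy <- function(X, y, fraction = 0.67) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  if (max(dy) <= 0) {
    stop("y is constant: SPXY's Y-space distance is degenerate; use kennard_stone instead",
         call. = FALSE)
  }
  if (max(dx) <= 0) {
    stop("all spectra are identical: SPXY's X-space distance is degenerate",
         call. = FALSE)
  }
  D <- dx / max(dx) + dy / max(dy)
  ncal <- floor(fraction * n + 0.5)  # round half up
  ncal <- max(2L, min(as.integer(ncal), n - 1L))
  cal <- ks_from_dist(D, ncal)
  structure(list(calibration_idx = cal,
                 prediction_idx = setdiff(seq_len(n), cal),
                 fraction = fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction (fraction %.2f)\n",
              length(x$calibration_idx), length(x$prediction_idx), x$fraction))
  invisible(x)
}
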