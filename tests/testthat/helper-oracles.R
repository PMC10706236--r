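# Independent oracles and small fixtures shared across test files.

# Natural cubic smoothing spline solved directly from the penalized
# least-squares normal equations (Green & Silverman band-matrix form):
# minimize p * sum((y - f)^2) + (1 - p) * int f''(x)^2 dx
# => f = (I + lambda K)^{-1} y with lambda = (1 - p) / p.
# Independent of stats::smooth.spline, which the package delegates to.
reinsch_spline <- function(x, y, p) {
  n <- length(x)
  h <- diff(x)
  D <- matrix(0, n - 2, n)
  W <- matrix(0, n - 2, n - 2)
  for (i in 1:(n - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    W[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < n - 2) {
      W[i, i + 1] <- h[i + 1] / 6
      W[i + 1, i] <- h[i + 1] / 6
    }
  }
  K <- t(D) %*% solve(W, D)
  lambda <- (1 - p) / p
  drop(solve(diag(n) + lambda * K, y))
}

# Step-wise exhaustive verification of the Kennard-Stone max-min property:
# checks that `sel` starts at a maximal-distance pair and that each later
# pick attains the maximum over all remaining candidates of the minimum
# distance to the already-selected set (ties allowed).
verify_kennard_stone <- function(D, sel) {
  n <- nrow(D)
  maxd <- max(D)
  if (D[sel[1], sel[2]] < maxd - 1e-12) return(FALSE)
  for (s in seq(3, length(sel))) {
    chosen <- sel[seq_len(s - 1)]
    remaining <- setdiff(seq_len(n), chosen)
    mind <- vapply(remaining, function(i) min(D[i, chosen]), numeric(1))
    if (mind[match(sel[s], remaining)] < max(mind) - 1e-12) return(FALSE)
  }
  TRUE
}

# Small generator configuration: 8 samples x 2 replicates on a short grid,
# with bands placed inside that grid (centers in nm chosen so 1e7/nm falls
# in 4000..4400 cm-1).
tiny_band_table <- function() {
  data.frame(
    constituent = c("protein", "lipid", "water"),
    center_nm = c(2439, 2381, 2326),   # ~4100, ~4200, ~4300 cm-1
    width_nm = c(25, 25, 25),
    amplitude = c(0.8, 1.0, 0.9),
    stringsAsFactors = FALSE)
}

tiny_config <- function(seed = 1, n_samples = 8, bands = tiny_band_table(),
                        ...) {
  generator_config(n_samples = n_samples, n_replicates = 2,
                   wavenumber_start = 4000, wavenumber_stop = 4400,
                   wavenumber_step = 10, bands = bands, seed = seed, ...)
}

# Random valid spectra_set for round-trip property tests.
random_spectra_set <- function(seed, n_samples = 3, n_rep = 2, m = 6) {
  set.seed(seed)
  spectra_set(sort(runif(m, 4000, 9000)),
              matrix(runif(n_samples * n_rep * m), n_samples * n_rep),
              sample_ids = rep(sprintf("S%d", 1:n_samples), each = n_rep),
              replicate_ids = rep(1:n_rep, times = n_samples))
}
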