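#' Default NIR band assignment table
#'
#' Gaussian absorption bands used by the spectra generator, one row per
#' (constituent, band) pair. Centers sit at the classical NIR overtone and
#' combination regions of the constituents that dominate dry-cured meat:
#' C-H bands near 1200 nm (second overtone), 1735 nm (first overtone) and
#' 2325 nm (combination) for lipid and, more weakly, protein; the N-H
#' second-overtone region near 1450 nm for protein; the O-H first-overtone
#' / combination regions near 1450 and 1900 nm for water. Amplitudes are in
#' absorbance units per unit mass fraction; widths are Gaussian sigmas in nm.
#'
#' @return A data.frame with columns `constituent`, `center_nm`, `width_nm`,
#'   `amplitude`.
#' @export
default_band_table <- function() {
  data.frame(
    constituent = c("lipid", "lipid", "lipid",
                    "protein", "protein", "protein",
                    "water", "water"),
    center_nm = c(1200, 1735, 2325,
                  1450, 1200, 2325,
                  1450, 1900),
    width_nm  = c(45, 55, 60,
                  70, 50, 65,
                  85, 95),
    amplitude = c(0.55, 1.00, 0.80,
                  0.70, 0.25, 0.40,
                  0.50, 1.00),
    stringsAsFactors = FALSE)
}

#' Default sensory attribute targets
#'
#' Per-attribute (min, max, mean, sd) of the panel scores the generator aims
#' for: the descriptive statistics of the forty dry-cured loins that motivate
#' the calibration (nine-point intensity scale, n = 40).
#'
#' @return A data.frame with columns `attribute`, `min`, `max`, `mean`, `sd`.
#' @export
default_attribute_targets <- function() {
  data.frame(
    attribute = sensory_attributes(),
    min  = c(5.13, 1.11, 1.00, 2.88, 1.56, 2.44, 3.44, 2.13, 5.11, 4.56),
    max  = c(6.78, 2.38, 1.78, 6.11, 4.89, 6.56, 6.11, 5.44, 6.44, 6.33),
    mean = c(5.92, 1.50, 1.24, 4.05, 3.11, 3.90, 5.10, 3.62, 5.89, 5.67),
    sd   = c(0.38, 0.28, 0.19, 0.73, 0.85, 1.23, 0.64, 0.85, 0.33, 0.42),
    stringsAsFactors = FALSE)
}

# Loadings of each attribute on the standardized latent drivers. Signs follow
# the usual sensory interpretation: lipolysis products drive odor/flavor,
# water content drives juiciness, drying (anti-water) drives hardness and
# color saturation. Internal; retained on generated tables as ground truth.
default_attribute_weights <- function() {
  w <- rbind(
    "Odor"               = c(protein = 0.10, lipid = 0.55, water = 0.00, drying = 0.50),
    "Andros"             = c(protein = 0.20, lipid = 0.80, water = 0.00, drying = 0.10),
    "Scatol"             = c(protein = 0.00, lipid = 0.70, water = -0.30, drying = 0.00),
    "Lean color"         = c(protein = 0.40, lipid = 0.00, water = 0.00, drying = 0.60),
    "Fat color"          = c(protein = 0.00, lipid = 0.70, water = 0.00, drying = 0.30),
    "Hardness"           = c(protein = 0.30, lipid = -0.10, water = -0.40, drying = 0.55),
    "Juiciness"          = c(protein = 0.00, lipid = 0.15, water = 0.80, drying = -0.30),
    "Chewiness"          = c(protein = 0.60, lipid = 0.00, water = -0.25, drying = 0.40),
    "Flavor intensity"   = c(protein = 0.20, lipid = 0.40, water = 0.00, drying = 0.50),
    "Flavor persistence" = c(protein = 0.00, lipid = 0.60, water = -0.10, drying = 0.40))
  w
}

#' Configuration for the synthetic dry-cured loin dataset generator
#'
#' Bundles every knob of the generator: instrument geometry (wavenumber grid,
#' replicate count), constituent band model, per-replicate scatter and noise
#' scales, latent composition distribution, and the sensory score targets.
#'
#' @param n_samples Number of loin samples (default 40).
#' @param n_replicates Spectra measured per sample (default 3).
#' @param wavenumber_start,wavenumber_stop,wavenumber_step Grid in cm^-1
#'   (defaults 4000, 10000, 4; 1501 channels).
#' @param bands Band table as from [default_band_table()].
#' @param baseline Constant background absorbance added to every channel.
#' @param scatter_gain_sd SD of the per-replicate multiplicative gain
#'   (mean 1) emulating path-length/scatter variation.
#' @param scatter_offset_sd SD of the per-replicate additive offset (mean 0).
#' @param noise_sd SD of i.i.d. instrument noise per channel, absorbance.
#' @param dirichlet_mean Mean composition (protein, lipid, water fractions,
#'   summing to 1) of the Dirichlet latent distribution.
#' @param dirichlet_concentration Dirichlet concentration; larger means a
#'   tighter compositional spread.
#' @param attribute_targets Data frame as from [default_attribute_targets()].
#' @param attribute_weights Matrix of latent loadings per attribute.
#' @param nonlinearity In `[0, 1]`: 0 gives purely linear latent-to-score
#'   maps, 1 fully saturating (tanh) maps. Default 0.6.
#' @param sensory_noise_frac Panel noise SD as a fraction of each attribute's
#'   target SD. Default 0.05 (scores are means over a nine-member panel).
#' @param seed Integer seed making all three generator stages deterministic.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_samples = 40L,
                             n_replicates = 3L,
                             wavenumber_start = 4000,
                             wavenumber_stop = 10000,
                             wavenumber_step = 4,
                             bands = default_band_table(),
                             baseline = 0.1,
                             scatter_gain_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 1e-3,
                             dirichlet_mean = c(protein = 0.45, lipid = 0.15, water = 0.40),
                             dirichlet_concentration = 60,
                             attribute_targets = default_attribute_targets(),
                             attribute_weights = default_attribute_weights(),
                             nonlinearity = 0.6,
                             sensory_noise_frac = 0.05,
                             seed = 1L) {
  cfg <- structure(
    list(n_samples = as.integer(n_samples),
         n_replicates = as.integer(n_replicates),
         wavenumber_start = wavenumber_start,
         wavenumber_stop = wavenumber_stop,
         wavenumber_step = wavenumber_step,
         bands = bands, baseline = baseline,
         scatter_gain_sd = scatter_gain_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd,
         dirichlet_mean = dirichlet_mean,
         dirichlet_concentration = dirichlet_concentration,
         attribute_targets = attribute_targets,
         attribute_weights = attribute_weights,
         nonlinearity = nonlinearity,
         sensory_noise_frac = sensory_noise_frac,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_samples < 4L) {
    stop("n_samples must be at least 4 (SPXY and cross-validation need >= 4 samples)",
         call. = FALSE)
  }
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (cfg$wavenumber_step <= 0) stop("wavenumber_step must be > 0", call. = FALSE)
  if (cfg$wavenumber_stop <= cfg$wavenumber_start) {
    stop("wavenumber_stop must exceed wavenumber_start", call. = FALSE)
  }
  sds <- c(cfg$scatter_gain_sd, cfg$scatter_offset_sd, cfg$noise_sd,
           cfg$sensory_noise_frac)
  if (any(sds < 0)) stop("noise and scatter SDs must be >= 0", call. = FALSE)
  if (cfg$nonlinearity < 0 || cfg$nonlinearity > 1) {
    stop("nonlinearity must lie in [0, 1]", call. = FALSE)
  }
  m <- cfg$dirichlet_mean
  if (length(m) != 3 || any(m <= 0) || abs(sum(m) - 1) > 1e-9) {
    stop("dirichlet_mean must be three positive fractions summing to 1",
         call. = FALSE)
  }
  if (cfg$dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  }
  tg <- cfg$attribute_targets
  need <- c("attribute", "min", "max", "mean", "sd")
  if (!all(need %in% names(tg))) {
    stop("attribute_targets needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(tg$attribute, sensory_attributes())
  if (length(unknown)) {
    stop(sprintf("unknown attribute(s) in targets: %s; valid names are: %s",
                 paste(unknown, collapse = ", "),
                 paste(sensory_attributes(), collapse = ", ")), call. = FALSE)
  }
  if (any(!(tg$min < tg$mean & tg$mean < tg$max))) {
    bad <- tg$attribute[!(tg$min < tg$mean & tg$mean < tg$max)]
    stop("attribute targets must satisfy min < mean < max; violated for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tg$sd < 0)) stop("attribute target sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Wavenumber grid of a generator configuration
#' @param config A [generator_config()].
#' @return Numeric vector in cm^-1.
#' @export
wavenumber_grid <- function(config) {
  seq(config$wavenumber_start, config$wavenumber_stop,
      by = config$wavenumber_step)
}

#' Draw latent compositions
#'
#' Samples per-loin (protein, lipid, water) mass fractions from a Dirichlet
#' distribution with the configured mean and concentration, and derives a
#' drying index in `[0, 1]` as a deterministic decreasing function of the
#' water fraction (drier products have lost more water).
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `sample_id`, `protein_frac`,
#'   `lipid_frac`, `water_frac`, `drying_index`.
#' @export
generate_latents <- function(config) {
  validate_generator_config(config)
  n <- config$n_samples
  alpha <- config$dirichlet_concentration * config$dirichlet_mean
  with_local_seed(derive_seed(config$seed, "latents"), {
    g <- matrix(rgamma(n * 3, shape = rep(alpha, each = n)), nrow = n)
    fr <- g / rowSums(g)
    colnames(fr) <- c("protein_frac", "lipid_frac", "water_frac")
    # theoretical Dirichlet moments, so the drying map does not depend on
    # the batch actually drawn
    a0 <- sum(alpha)
    mu_w <- alpha[3] / a0
    sd_w <- sqrt(mu_w * (1 - mu_w) / (a0 + 1))
    drying <- pnorm(-(fr[, "water_frac"] - mu_w) / sd_w)
    data.frame(sample_id = sprintf("S%02d", seq_len(n)),
               protein_frac = fr[, "protein_frac"],
               lipid_frac = fr[, "lipid_frac"],
               water_frac = fr[, "water_frac"],
               drying_index = drying,
               stringsAsFactors = FALSE)
  })
}

# Pure constituent spectra on the wavenumber grid (constituents x channels).
constituent_spectra <- function(config, wn = wavenumber_grid(config)) {
  bands <- config$bands
  cons <- unique(bands$constituent)
  S <- matrix(0, nrow = length(cons), ncol = length(wn),
              dimnames = list(cons, NULL))
  for (i in seq_len(nrow(bands))) {
    center_wn <- 1e7 / bands$center_nm[i]
    if (center_wn < min(wn) || center_wn > max(wn)) {
      warning(sprintf("band at %g nm (%.0f cm-1) lies outside the grid; skipped",
                      bands$center_nm[i], center_wn), call. = FALSE)
      next
    }
    sigma_wn <- 1e7 * bands$width_nm[i] / bands$center_nm[i]^2
    S[bands$constituent[i], ] <- S[bands$constituent[i], ] +
      bands$amplitude[i] * exp(-(wn - center_wn)^2 / (2 * sigma_wn^2))
  }
  S
}

#' Generate replicate NIR spectra from latent compositions
#'
#' Each ideal spectrum is a composition-weighted sum of the constituent band
#' profiles plus a constant baseline; each replicate then receives a
#' multiplicative gain (mean 1), an additive offset (mean 0) — the scatter
#' effects that MSC/SNV pre-treatments exist to remove — and i.i.d.
#' channel noise.
#'
#' @param latents Output of [generate_latents()].
#' @param config The same [generator_config()].
#' @return A [spectra_set()] with `n_samples * n_replicates` rows.
#' @export
generate_spectra <- function(latents, config) {
  validate_generator_config(config)
  if (nrow(latents) < 1) stop("latents must be non-empty", call. = FALSE)
  wn <- wavenumber_grid(config)
  S <- constituent_spectra(config, wn)
  fr <- as.matrix(latents[, c("protein_frac", "lipid_frac", "water_frac")])
  colnames(fr) <- c("protein", "lipid", "water")
  ideal <- fr[, rownames(S), drop = FALSE] %*% S + config$baseline
  n <- nrow(latents)
  r <- config$n_replicates
  with_local_seed(derive_seed(config$seed, "spectra"), {
    gains <- 1 + rnorm(n * r, sd = config$scatter_gain_sd)
    offsets <- rnorm(n * r, sd = config$scatter_offset_sd)
    A <- matrix(0, nrow = n * r, ncol = length(wn))
    for (i in seq_len(n)) {
      for (j in seq_len(r)) {
        row <- (i - 1L) * r + j
        A[row, ] <- ideal[i, ] * gains[row] + offsets[row]
      }
    }
    if (config$noise_sd > 0) {
      A <- A + matrix(rnorm(length(A), sd = config$noise_sd), nrow = nrow(A))
    }
    spectra_set(wn, A,
                sample_ids = rep(latents$sample_id, each = r),
                replicate_ids = rep(seq_len(r), times = n))
  })
}

#' Generate sensory scores from latent compositions
#'
#' Each attribute is a monotone, mildly saturating function of a weighted
#' combination of the standardized latent drivers (protein, lipid, water
#' fractions and the drying index), plus Gaussian panel noise, affinely
#' rescaled to the configured target mean and SD and clipped to the 1--9
#' scale. The ground-truth drivers are retained as attributes of the result
#' for parameter-recovery tests.
#'
#' @param latents Output of [generate_latents()].
#' @param config The same [generator_config()].
#' @return A [sensory_table()] with one row per sample. Attributes
#'   `"latents"`, `"weights"` and `"nonlinearity"` carry the ground truth.
#' @export
generate_sensory <- function(latents, config) {
  validate_generator_config(config)
  tg <- config$attribute_targets
  W <- config$attribute_weights
  unknown <- setdiff(rownames(W), sensory_attributes())
  if (length(unknown)) {
    stop(sprintf("unknown attribute(s) in weights: %s; valid names are: %s",
                 paste(unknown, collapse = ", "),
                 paste(sensory_attributes(), collapse = ", ")), call. = FALSE)
  }
  alpha <- config$dirichlet_concentration * config$dirichlet_mean
  a0 <- sum(alpha)
  mu <- alpha / a0
  sdv <- sqrt(mu * (1 - mu) / (a0 + 1))
  fr <- as.matrix(latents[, c("protein_frac", "lipid_frac", "water_frac")])
  Z <- sweep(sweep(fr, 2, mu), 2, sdv, "/")
  colnames(Z) <- c("protein", "lipid", "water")
  Z <- cbind(Z, drying = -Z[, "water"])  # drying index is pnorm(-z_water)
  n <- nrow(latents)
  nl <- config$nonlinearity
  with_local_seed(derive_seed(config$seed, "sensory"), {
    scores <- matrix(NA_real_, nrow = n, ncol = nrow(tg),
                     dimnames = list(NULL, tg$attribute))
    for (k in seq_len(nrow(tg))) {
      at <- tg$attribute[k]
      if (!at %in% rownames(W)) {
        stop(sprintf("no latent weights defined for attribute '%s'", at),
             call. = FALSE)
      }
      u <- drop(Z %*% W[at, ])
      su <- sd(u)
      us <- if (su > 0) u / su else u
      v <- (1 - nl) * us + nl * tanh(1.5 * us)
      v <- v + config$sensory_noise_frac * rnorm(n)
      sv <- sd(v)
      z <- if (sv > 0) (v - mean(v)) / sv else v - mean(v)
      scores[, k] <- pmin(9, pmax(1, tg$mean[k] + tg$sd[k] * z))
    }
    out <- sensory_table(latents$sample_id, as.data.frame(scores, check.names = FALSE))
    attr(out, "latents") <- latents
    attr(out, "weights") <- W
    attr(out, "nonlinearity") <- nl
    out
  })
}

#' Simulate a complete paired dataset
#'
#' Convenience wrapper running [generate_latents()], [generate_spectra()] and
#' [generate_sensory()] under one configuration.
#'
#' @param config A [generator_config()].
#' @return List with elements `latents`, `spectra`, `sensory`, `config`.
#' @export
simulate_loin_dataset <- function(config = generator_config()) {
  latents <- generate_latents(config)
  list(latents = latents,
       spectra = generate_spectra(latents, config),
       sensory = generate_sensory(latents, config),
       config = config)
}
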