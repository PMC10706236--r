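test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_loin_dataset(cfg)
  b <- simulate_loin_dataset(cfg)
  expect_identical(a$latents, b$latents)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(as.data.frame(a$sensory), as.data.frame(b$sensory))
})

test_that("latent compositions live on the simplex with a drying index in [0,1]", {
  lat <- generate_latents(tiny_config(seed = 2))
  fr <- as.matrix(lat[, c("protein_frac", "lipid_frac", "water_frac")])
  expect_true(all(fr > 0))
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  expect_true(all(lat$drying_index >= 0 & lat$drying_index <= 1))
})

test_that("default configuration reproduces the study geometry", {
  cfg <- generator_config(seed = 1)
  lat <- generate_latents(cfg)
  expect_equal(nrow(lat), 40)
  sp <- generate_spectra(lat, cfg)
  expect_equal(dim(sp$absorbance), c(120, 1501))      # 40 x 3; (10000-4000)/4+1
  expect_equal(length(unique(sp$sample_ids)), 40)
  sens <- generate_sensory(lat, cfg)
  expect_equal(nrow(sens), 40)
  expect_setequal(setdiff(names(sens), "sample_id"), sensory_attributes())
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(generator_config(n_samples = 3), "at least 4")
  expect_error(generator_config(wavenumber_step = 0), "step")
  expect_error(generator_config(noise_sd = -1), ">= 0")
  tg <- default_attribute_targets()
  tg$mean[1] <- tg$max[1] + 1
  expect_error(generator_config(attribute_targets = tg), "min < mean < max")
  tg2 <- default_attribute_targets()
  tg2$attribute[3] <- "Crunchiness"
  expect_error(generator_config(attribute_targets = tg2),
               "Crunchiness.*valid names")
})

test_that("replicates are bit-identical when scatter and noise are disabled", {
  cfg <- tiny_config(seed = 5, scatter_gain_sd = 0, scatter_offset_sd = 0,
                     noise_sd = 0)
  ds <- simulate_loin_dataset(cfg)
  A <- ds$spectra$absorbance
  ids <- ds$spectra$sample_ids
  for (s in unique(ids)) {
    rows <- A[ids == s, , drop = FALSE]
    expect_identical(rows[1, ], rows[2, ])
  }
})

test_that("band centers map from nm to the nearest wavenumber channel", {
  bands <- data.frame(constituent = "water", center_nm = 1450,
                      width_nm = 60, amplitude = 1)
  cfg <- generator_config(bands = bands, baseline = 0, seed = 1)
  S <- nirsense:::constituent_spectra(cfg)
  wn <- wavenumber_grid(cfg)
  peak <- wn[which.max(S["water", ])]
  expect_lte(abs(peak - 1e7 / 1450), cfg$wavenumber_step / 2)  # ~6896.55
})

test_that("bands outside the grid are skipped with a warning", {
  bands <- rbind(tiny_band_table(),
                 data.frame(constituent = "water", center_nm = 1450,
                            width_nm = 60, amplitude = 1))
  cfg <- tiny_config(seed = 1, bands = bands)  # 1450 nm = 6897 cm-1, off-grid
  lat <- generate_latents(cfg)
  expect_warning(generate_spectra(lat, cfg), "outside the grid")
})

test_that("sensory scores stay on the 1-9 scale and hit the target moments", {
  cfg <- generator_config(seed = 3)
  ds <- simulate_loin_dataset(cfg)
  S <- sensory_matrix(ds$sensory)
  expect_true(all(S >= 1 & S <= 9))
  # generator targets the study means; 3 standard errors of the mean
  expect_lt(abs(mean(S[, "Hardness"]) - 3.90), 3 * 1.23 / sqrt(40))
  expect_lt(abs(mean(S[, "Odor"]) - 5.92), 3 * 0.38 / sqrt(40))
})

test_that("with no noise and a linear map, scores are an affine function of the latents", {
  cfg <- generator_config(seed = 8, nonlinearity = 0, sensory_noise_frac = 0)
  ds <- simulate_loin_dataset(cfg)
  # Juiciness targets keep all scores far from the 1/9 clip bounds
  fit <- lm(ds$sensory$Juiciness ~ protein_frac + lipid_frac + water_frac,
            data = ds$latents)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("default spectra are strictly positive", {
  ds <- simulate_loin_dataset(generator_config(seed = 4))
  expect_true(all(ds$spectra$absorbance > 0))
})

test_that("without scatter, SNV and MSC nearly preserve band-area ordering", {
  # per-row standardization is composition-dependent, so exact rank equality
  # cannot hold; in the dominant lipid (1735 nm) and water (1900 nm) band
  # windows the ordering is preserved to high rank correlation
  cfg <- generator_config(seed = 4, scatter_gain_sd = 0,
                          scatter_offset_sd = 0, noise_sd = 0)
  ds <- simulate_loin_dataset(cfg)
  pa <- align_spectra_sensory(ds$spectra, ds$sensory)
  wn <- pa$wavenumbers
  for (w in list(c(5600, 5950), c(5100, 5450))) {
    win <- wn >= w[1] & wn <= w[2]
    a0 <- rowSums(pa$X[, win])
    expect_gt(cor(a0, rowSums(snv(pa$X)[, win]), method = "spearman"), 0.95)
    expect_gt(cor(a0, rowSums(msc(pa$X)$spectra[, win]), method = "spearman"),
              0.95)
  }
})
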