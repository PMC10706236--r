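---
title: "Calibrating sensory attributes against NIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating sensory attributes against NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Descriptive sensory analysis of dry-cured meat — a trained panel scoring
odor, boar-taint notes (androsterone, scatol), lean and fat color, hardness,
juiciness, chewiness and flavor intensity/persistence on a 1–9 intensity
scale — is slow and expensive. Fourier-transform near-infrared (NIR)
spectroscopy over 4000–10,000 cm⁻¹ probes the C–H, N–H and O–H
overtone/combination bands of the product's dominant constituents (lipids,
proteins, water), whose balance also drives the sensory experience. The
package implements the full chemometric chain that turns replicate NIR
spectra plus panel scores into validated per-attribute calibration models:

1. cubic smoothing-spline noise removal,
2. scatter correction (MSC or SNV) or finite-difference derivatives,
3. column normalization fitted on calibration samples only,
4. SPXY partitioning into calibration (67%) and prediction (33%) subsets,
5. ε- or ν-support-vector regression (four kernels), hyperparameters tuned
   by hybrid particle swarm + pattern search minimizing the pooled 5-fold
   cross-validated RMSE,
6. figures of merit: RMSEC/RMSEP, R², RSD%, the elliptical joint confidence
   region (EJCR) of the observed-versus-predicted line, and the
   Durbin–Watson residual test,

plus a PLS1 baseline used to judge whether the spectra–score relation is
adequately linear.

```{r, eval = FALSE}
library(nirsense)
ds <- simulate_loin_dataset(generator_config(seed = 1))
run <- run_grid(ds$spectra, ds$sensory,
                grid_spec(pre_treatments = "MSC", normalizations = "minmax",
                          svr_types = "epsilon", kernels = "radial_base"),
                pso = pso_preset("ci"), seed = 1)
run$best
```

# The synthetic data generator

No public spectral dataset accompanies this kind of study, so the package
ships a generator whose defaults are the study conditions themselves: 40
samples, 3 replicate spectra each, a 4000–10,000 cm⁻¹ grid at 4 cm⁻¹
(1501 channels), and per-attribute score targets with the descriptive
statistics of a 40-loin panel (e.g. hardness mean 3.90, SD 1.23 on the 1–9
scale).

**Latent composition.** Each sample draws (protein, lipid, water) mass
fractions from a Dirichlet distribution with mean (0.45, 0.15, 0.40) —
typical of a dry-cured loin — and concentration 60, giving a compositional
spread of a few percentage points, enough to span the observed score
ranges without producing implausible products. A drying index in [0, 1] is
a deterministic decreasing function of the water fraction
(`pnorm(-z_water)`). Making it deterministic is intentional: the spectra
are purely composition-driven, so any independent drying component would
be spectrally invisible and would put an artificial ceiling on attribute
recovery; tying it to water keeps "drying" predictable from the spectra,
as it is in practice where drying *is* water loss.

**Spectra.** Each constituent contributes Gaussian bands (in wavenumber
space — the simplest defensible line shape) at the classical NIR
assignments: C–H near 1200, 1735 and 2325 nm (mostly lipid, weakly
protein), N–H near 1450 nm (protein), O–H near 1450 and 1900 nm (water);
centers in nm map to the grid through λ[nm] = 10⁷/ν̃[cm⁻¹]. A constant
baseline of 0.1 AU keeps absorbances strictly positive. Every replicate
then receives a multiplicative gain (mean 1, SD 0.05) and additive offset
(mean 0, SD 0.02) — the scatter effects MSC/SNV exist to remove, applied
per replicate so that scatter correction does real work before replicate
averaging — plus i.i.d. channel noise (SD 10⁻³ AU).

**Scores.** Each attribute is a weighted combination of the standardized
latent drivers passed through a monotone saturating map,
`(1-ν)·z + ν·tanh(1.5 z)` with nonlinearity ν = 0.6 by default, plus
Gaussian panel noise with SD equal to 5% of the attribute's target SD,
then affinely rescaled to the target mean/SD and clipped to [1, 9]. The 5%
noise level reflects that each "score" stands for the mean of a trained
nine-member panel; it corresponds to a noise ceiling of R² ≈ 0.9975,
consistent with the calibration-grade prediction accuracies such studies
report. The linearity knob is exposed rather than fixed because whether
spectra–sensory relations are nonlinear a priori is an open question; the
default is nonlinear enough that a linear PLS baseline is measurably
handicapped while kernel SVR is not.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: instrument drift and wavelength misalignment,
baseline curvature beyond affine scatter, panelist disagreement structure
(scores are exchangeable Gaussian around the latent truth), inter-attribute
correlation beyond what the shared latents induce, and any non-constituent
chemistry (salt, paprika, proteolysis products). Results on the generator
bound what the pipeline can do when its assumptions hold; they do not
certify performance on instrument data.

# Numerical conventions

* **Smoothing spline.** The parameter p ∈ (0, 1] follows the classical
  penalized least-squares trade-off `p·Σ(y−f)² + (1−p)·∫f″²` with x in
  original wavenumber units (the convention of MATLAB's `csaps`, in which
  a smoothing parameter of 0.01 is meaningful); internally this becomes
  `stats::smooth.spline(lambda = (1−p)/(p·r³))` with r the wavenumber
  range. p = 1 reproduces the data at the channels; p → 0 approaches the
  least-squares line. The implementation is verified against a direct
  Reinsch (band-matrix) solve of the same objective.
* **MSC.** Reference = mean spectrum of the rows it is fitted on; each row
  is regressed on the reference by OLS and corrected as (row − a)/b. The
  reference is part of the fitted state and is reapplied unchanged to
  prediction data.
* **SNV** uses the n−1 standard deviation. Constant rows are an error.
* **Derivatives** are central differences on the uniform grid; endpoints
  use one-sided first differences (order 1) or copy the adjacent interior
  value (order 2) so the channel count never changes across
  pre-treatments.
* **Normalizations** (`mean_center`, `autoscale`, `pareto`,
  `poisson` = x/√mean, `minmax` to [−1, +1]) are fitted column-wise on
  calibration rows only; minmax extrapolates without clipping. "Poisson"
  follows the standard chemometric scaling family; it is the reading of an
  ambiguous label in the source material's normalization list.
* **SPXY.** Combined distance d = dx/max(dx) + dy/max(dy) (Euclidean in
  each space), Kennard–Stone on d, calibration size = round-half-up of
  0.67·n (27/13 at n = 40). Ties break to the lowest index, making the
  split deterministic. Each attribute gets its own split because the
  Y-space distance is attribute-specific; a shared split can be supplied
  explicitly for comparability. Distances are computed on pre-treated,
  un-normalized spectra. Because a split does not yet exist at selection
  time, the selection stage uses the all-sample MSC reference; every
  fitted quantity (MSC reference, normalization, hyperparameters) is then
  refitted on calibration rows only, so prediction rows never influence
  the model (tested).
* **RMSECV** pools squared errors over all folds (√(Σe²/n)), not the mean
  of per-fold RMSEs; both conventions exist, so the choice is pinned and a
  flag exposes the other. Folds are contiguous blocks of a seeded shuffle
  and are identical for every candidate within one tuning run.
* **SVR** solves the standard ε-/ν-SVR dual via libsvm (package `e1071`),
  without internal rescaling. The solver is treated as a pluggable
  component: tests validate it against an independent QP implementation
  (`kernlab`) and against analytic tube properties. When the ε-tube covers
  all targets the dual is empty and the model is the constant −ρ. During
  tuning, X is projected onto an orthonormal basis of its row space —
  every licensed kernel depends on X only through inner products or
  distances, so objective values are unchanged while each of the thousands
  of solver calls sheds the 1501-channel overhead.
* **PSO + pattern search.** Global-best swarm (inertia 0.729,
  cognitive/social 1.49445), velocity clamped to half the box, boundary
  reflection, log₁₀ search for C, ε, γ; stagnation patience; then
  coordinate pattern search from the swarm optimum with geometric step
  contraction, which by construction never returns a worse point. Default
  bounds C ∈ [10⁻², 10²], ε ∈ [10⁻³, 1], γ ∈ [10⁻³, 1] (log), ν ∈
  (0.01, 0.99), coef0 ∈ [−1, 1], integer degree 2–5 rounded at
  evaluation; reported optima of comparable studies lie inside these
  boxes. Swarm settings are declared defaults, not inferred ones; the
  `"ci"` preset (swarm 10, 20 iterations) keeps a ten-attribute run in the
  minutes range and is what the shipped tests and the acceptance script
  use, while `"paper"` (swarm 20, 50 iterations) is the thorough preset.
* **Figures of merit.** R² = 1 − SSE/SST (not squared correlation). RSD% =
  100·RMSEP/mean(observed prediction values); the literature is ambiguous
  between mean-, range- and SD-denominators, so the convention is declared
  inside every report. EJCR regresses predicted on observed and tests
  whether (intercept, slope) = (0, 1) lies inside the F(2, n−2) ellipse;
  its size is verified by Monte-Carlo at the study's prediction-set size
  (n = 13). The Durbin–Watson probability uses the large-sample normal
  approximation DW ~ N(2, 4/n) for i.i.d. residuals — adequate at n
  between 13 and 40 per simulation, and far simpler than the exact
  Imhof/Pan distribution, which is out of scope.
* **Model selection.** Best grid cell per attribute = lowest RMSECV, with
  prediction RMSEP only as tie-break — selecting on the prediction set
  would be leakage. A flag-free alternative is deliberate: the records
  retain every cell so any other criterion can be applied post hoc.
* **Replicates** are averaged per sample before modeling by default
  (keeping n = 40); `replicate_policy = "keep"` expands scores to
  replicates instead. Whether the original workflow averaged or kept
  replicates is not documented; both are supported, neither asserted.

# Reproducibility

Every stochastic step (generator, fold shuffle, swarm) derives its seed
deterministically from one master seed and a stage label, so a saved run
manifest (`run_manifest()` → `run_from_manifest()`) reruns to a
bit-identical `report.csv`. Model bundles serialize with the standard R
serialization (`save_model()`/`load_model()`); configurations, splits and
manifests serialize as JSON with 17-significant-digit numbers so doubles
round-trip exactly.

# Known limitations

* Rank ordering of raw band-area features is only *nearly* preserved by
  SNV/MSC even without scatter: per-row standardization is
  composition-dependent, so exact rank invariance is impossible whenever
  rows differ in composition. In the dominant lipid (1735 nm) and water
  (1900 nm) windows the preservation is high (Spearman > 0.95, tested);
  in weak mixed-band windows it degrades.
* At the default nonlinearity the most nearly linear attribute can
  legitimately select the linear kernel by RMSECV; the radial-kernel win
  is a property of strongly nonlinear score maps, and is tested at that
  setting.
* The Durbin–Watson probability is approximate; EJCR assumes Gaussian
  residuals; both are calibrated by simulation, not exact.
* Problem sizes in the shipped tests are the study geometry (40 × 3 ×
  1501) with the `"ci"` optimizer preset and 3 seeds for the end-to-end
  recovery check; larger swarms and more seeds sharpen the estimates but
  do not change the qualitative findings.
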