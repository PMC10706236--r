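#' Specify the model grid
#'
#' Cartesian grid of pre-treatment, normalization, SVR type and kernel to be
#' tuned per attribute. Defaults cover the full grid; restrict any axis to
#' shrink the run.
#'
#' @param pre_treatments Subset of `"MSC"`, `"SNV"`, `"D1"`, `"D2"`.
#' @param normalizations Subset of `"mean_center"`, `"autoscale"`,
#'   `"pareto"`, `"poisson"`, `"minmax"`.
#' @param svr_types Subset of `"epsilon"`, `"nu"`.
#' @param kernels Subset of `"radial_base"`, `"linear"`, `"polynomial"`,
#'   `"sigmoid"`.
#' @param attributes Subset of [sensory_attributes()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(pre_treatments = c("MSC", "SNV", "D1", "D2"),
                      normalizations = c("mean_center", "autoscale", "pareto",
                                         "poisson", "minmax"),
                      svr_types = c("epsilon", "nu"),
                      kernels = c("radial_base", "linear", "polynomial",
                                  "sigmoid"),
                      attributes = sensory_attributes()) {
  check_axis <- function(x, allowed, what) {
    if (length(x) == 0) stop(what, " axis must be non-empty", call. = FALSE)
    bad <- setdiff(x, allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s: %s (allowed: %s)", what,
                   paste(bad, collapse = ", "),
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
    x
  }
  structure(list(
    pre_treatments = check_axis(pre_treatments, c("MSC", "SNV", "D1", "D2"),
                                "pre-treatment"),
    normalizations = check_axis(normalizations,
                                c("mean_center", "autoscale", "pareto",
                                  "poisson", "minmax"), "normalization"),
    svr_types = check_axis(svr_types, c("epsilon", "nu"), "SVR type"),
    kernels = check_axis(kernels, c("radial_base", "linear", "polynomial",
                                    "sigmoid"), "kernel"),
    attributes = check_axis(attributes, sensory_attributes(), "attribute")),
    class = "grid_spec")
}

# Bundle of everything needed to predict new raw spectra: smoothing
# parameter, pre-treatment (with its calibration-fitted MSC reference),
# calibration-fitted normalizer and the regression fit.
calibration_model <- function(smoothing_p, pre_treatment, msc_reference,
                              normalizer, regressor, wavenumbers,
                              calibration_ids, replicate_policy = "mean") {
  structure(list(smoothing_p = smoothing_p, pre_treatment = pre_treatment,
                 msc_reference = msc_reference, normalizer = normalizer,
                 regressor = regressor, wavenumbers = wavenumbers,
                 calibration_ids = calibration_ids,
                 replicate_policy = replicate_policy),
            class = "calibration_model")
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    if (length(newdata$wavenumbers) != length(object$wavenumbers) ||
        any(newdata$wavenumbers != object$wavenumbers)) {
      stop(sprintf("expected %d channels on the training wavenumber grid",
                   length(object$wavenumbers)), call. = FALSE)
    }
    sm <- smooth_spectra(newdata, object$smoothing_p)
    pt <- apply_pretreatment(sm, object$pre_treatment,
                             msc_reference = object$msc_reference)
    ids <- unique(pt$spectra$sample_ids)
    X <- t(vapply(ids, function(s) {
      colMeans(pt$spectra$absorbance[pt$spectra$sample_ids == s, ,
                                     drop = FALSE])
    }, numeric(length(object$wavenumbers))))
    setNames(predict(object$regressor, apply_normalizer(X, object$normalizer)),
             ids)
  } else {
    X <- as.matrix(newdata)
    predict(object$regressor, apply_normalizer(X, object$normalizer))
  }
}

# Mean spectrum over the replicate rows belonging to the given sample ids.
calibration_msc_reference <- function(spectra, cal_ids) {
  colMeans(spectra$absorbance[spectra$sample_ids %in% cal_ids, , drop = FALSE])
}

#' Run the calibration grid
#'
#' For every attribute and grid cell: pre-treat the replicate spectra,
#' partition samples by SPXY on the pre-treated (un-normalized) X and that
#' attribute's scores, fit the normalization on the calibration subset,
#' tune the SVR hyperparameters by PSO + pattern search against the pooled
#' 5-fold RMSECV on the calibration subset, refit on the full calibration
#' subset and evaluate the figures of merit on the held-out prediction
#' subset. The best cell per attribute minimizes RMSECV, with prediction
#' RMSEP as tie-break.
#'
#' SPXY needs a pre-treated X before any split exists, so the selection
#' stage uses the all-sample MSC reference; all model state (MSC reference,
#' normalization, hyperparameters) is then refitted on the calibration
#' subset only.
#'
#' @param spectra A [spectra_set()] (replicate level).
#' @param sensory A [sensory_table()].
#' @param grid A [grid_spec()].
#' @param pso A [pso_config()] (its seed field is ignored; per-cell seeds
#'   derive from `seed`).
#' @param seed Master seed; every cell derives its own PSO and CV seeds
#'   from it.
#' @param smoothing_p Smoothing-spline parameter applied before everything.
#' @param fraction SPXY calibration fraction.
#' @param replicate_policy Passed to [align_spectra_sensory()].
#' @param splits Optional named list (by attribute) of precomputed
#'   `split_result`s, bypassing SPXY (splits are then shared across
#'   pre-treatments).
#' @param alpha EJCR significance level.
#' @return An object of class `grid_run`: `records` (one per cell x
#'   attribute, each with `tuning`, `merit`, `model`, `split`), `best`
#'   (data.frame, one row per attribute) and the run settings.
#' @export
run_grid <- function(spectra, sensory, grid = grid_spec(),
                     pso = pso_preset("ci"), seed = 1L, smoothing_p = 0.01,
                     fraction = 0.67, replicate_policy = "mean",
                     splits = NULL, alpha = 0.05) {
  validate_spectra_set(spectra)
  smoothed <- smooth_spectra(spectra, smoothing_p)
  # selection-stage pre-treatment (all-sample MSC reference) and alignment
  sel <- list()
  for (pre in grid$pre_treatments) {
    pt <- apply_pretreatment(smoothed, pre)
    sel[[pre]] <- align_spectra_sensory(pt$spectra, sensory, replicate_policy)
  }
  scores <- sensory_matrix(sel[[grid$pre_treatments[1]]]$sensory)
  records <- list()
  for (attribute in grid$attributes) {
    y <- scores[, attribute]
    for (pre in grid$pre_treatments) {
      Xsel <- sel[[pre]]$X
      split <- if (!is.null(splits)) splits[[attribute]] else {
        spxy(Xsel, y, fraction)
      }
      cal_ids <- rownames(Xsel)[split$calibration_idx]
      # modeling-stage pre-treatment: MSC reference from calibration rows
      if (pre == "MSC") {
        ref <- calibration_msc_reference(smoothed, cal_ids)
        ptm <- apply_pretreatment(smoothed, pre, msc_reference = ref)
        Xm <- align_spectra_sensory(ptm$spectra, sensory, replicate_policy)$X
        msc_ref <- ref
      } else {
        Xm <- Xsel
        msc_ref <- NULL
      }
      for (norm in grid$normalizations) {
        for (svr_type in grid$svr_types) {
          for (kernel in grid$kernels) {
            label <- paste(attribute, pre, norm, svr_type, kernel, sep = "|")
            cell_seed <- derive_seed(seed, label)
            rec <- tryCatch({
              nrm <- fit_normalizer(Xm[split$calibration_idx, , drop = FALSE],
                                    norm)
              Xn <- apply_normalizer(Xm, nrm)
              cfg <- pso
              cfg$seed <- cell_seed
              tr <- tune_svr(Xn[split$calibration_idx, , drop = FALSE],
                             y[split$calibration_idx],
                             svr_type = svr_type, kernel = kernel,
                             config = cfg,
                             cv_seed = derive_seed(cell_seed, "cv"))
              reg <- fit_svr(Xn[split$calibration_idx, , drop = FALSE],
                             y[split$calibration_idx], tr$best_spec)
              mr <- merit_report(reg, Xn, y, split, attribute, alpha = alpha)
              model <- calibration_model(smoothing_p, pre, msc_ref, nrm, reg,
                                         spectra$wavenumbers, cal_ids,
                                         replicate_policy)
              list(attribute = attribute, pre_treatment = pre,
                   normalization = norm, svr_type = svr_type,
                   kernel = kernel, seed = cell_seed, split = split,
                   tuning = tr, merit = mr, model = model, error = NULL)
            }, error = function(e) {
              list(attribute = attribute, pre_treatment = pre,
                   normalization = norm, svr_type = svr_type,
                   kernel = kernel, seed = cell_seed, split = split,
                   tuning = NULL, merit = NULL, model = NULL,
                   error = conditionMessage(e))
            })
            records[[label]] <- rec
          }
        }
      }
    }
  }
  best <- best_per_attribute(records, grid$attributes)
  structure(list(records = records, best = best, grid = grid, pso = pso,
                 seed = seed, smoothing_p = smoothing_p, fraction = fraction,
                 replicate_policy = replicate_policy, alpha = alpha),
            class = "grid_run")
}

best_per_attribute <- function(records, attributes) {
  rows <- lapply(attributes, function(at) {
    recs <- Filter(function(r) r$attribute == at && is.null(r$error), records)
    if (length(recs) == 0) {
      stop(sprintf("every grid cell failed for attribute '%s'", at),
           call. = FALSE)
    }
    cv <- vapply(recs, function(r) r$tuning$best_rmsecv, numeric(1))
    rp <- vapply(recs, function(r) r$merit$rmsep, numeric(1))
    ord <- order(cv, rp)  # min RMSECV, RMSEP as tie-break
    r <- recs[[ord[1]]]
    sp <- r$tuning$best_spec
    cbind(data.frame(attribute = at,
                     pre_treatment = r$pre_treatment,
                     normalization = r$normalization,
                     svr_type = r$svr_type, kernel = r$kernel,
                     C = sp$C,
                     epsilon = sp$epsilon %||% NA_real_,
                     nu = sp$nu %||% NA_real_,
                     gamma = sp$gamma %||% NA_real_,
                     rmsecv = r$tuning$best_rmsecv,
                     stringsAsFactors = FALSE),
          r$merit[, setdiff(names(r$merit), "attribute"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.grid_run <- function(x, ...) {
  cat(sprintf("<grid_run> %d cells, %d attributes; best per attribute:\n",
              length(x$records), nrow(x$best)))
  print(x$best[, c("attribute", "pre_treatment", "normalization", "kernel",
                   "rmsecv", "rmsep", "r2_pred", "rsd_pred_pct")])
  invisible(x)
}

#' Write the per-attribute report table
#'
#' CSV with the merit columns in the conventional order: model parameters
#' (C, epsilon, gamma, ...), calibration RMSE and R-squared, prediction
#' RMSE and R-squared, RSD\%, then adequacy diagnostics.
#'
#' @param run A `grid_run` (or its `best` data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path) {
  best <- if (inherits(run, "grid_run")) run$best else run
  first <- c("attribute", "C", "epsilon", "nu", "gamma",
             "rmsec", "r2_cal", "rmsep", "r2_pred", "rsd_pred_pct",
             "ejcr_contains_ideal", "dw_statistic", "dw_probability",
             "rmsecv", "pre_treatment", "normalization", "svr_type", "kernel")
  best <- best[, c(first, setdiff(names(best), first)), drop = FALSE]
  write.csv(best, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Create a reproducible run manifest
#'
#' A manifest captures the data source (generator configuration or CSV
#' paths), the grid, the optimizer budget and every seed, so a run can be
#' reproduced bit-identically with [run_from_manifest()].
#'
#' @param generator Optional [generator_config()] (synthetic data source).
#' @param spectra_csv,sensory_csv Optional CSV paths (measured data source;
#'   exactly one source must be given).
#' @param grid A [grid_spec()].
#' @param pso A [pso_config()].
#' @param seed Master seed.
#' @param smoothing_p,fraction,replicate_policy As in [run_grid()].
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(generator = NULL, spectra_csv = NULL,
                         sensory_csv = NULL, grid = grid_spec(),
                         pso = pso_preset("ci"), seed = 1L,
                         smoothing_p = 0.01, fraction = 0.67,
                         replicate_policy = "mean") {
  if (is.null(generator) == (is.null(spectra_csv) && is.null(sensory_csv))) {
    stop("give exactly one data source: a generator config, or spectra_csv + sensory_csv",
         call. = FALSE)
  }
  if (is.null(generator) && (is.null(spectra_csv) || is.null(sensory_csv))) {
    stop("both spectra_csv and sensory_csv are required", call. = FALSE)
  }
  structure(list(generator = generator, spectra_csv = spectra_csv,
                 sensory_csv = sensory_csv, grid = grid, pso = pso,
                 seed = as.integer(seed), smoothing_p = smoothing_p,
                 fraction = fraction, replicate_policy = replicate_policy),
            class = "run_manifest")
}

#' Execute a run manifest
#'
#' Generates or reads the data, runs the grid and writes `report.csv`,
#' `splits/` (one JSON per attribute of the best models) and
#' `manifest.json` under `out_dir`. Rerunning the same manifest rewrites
#' bit-identical outputs.
#'
#' @param manifest A [run_manifest()].
#' @param out_dir Output directory (created if needed).
#' @return The `grid_run`, invisibly.
#' @export
run_from_manifest <- function(manifest, out_dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!is.null(manifest$generator)) {
    ds <- simulate_loin_dataset(manifest$generator)
    spectra <- ds$spectra; sensory <- ds$sensory
  } else {
    spectra <- read_spectra(manifest$spectra_csv)
    sensory <- read_sensory(manifest$sensory_csv)
  }
  run <- run_grid(spectra, sensory, grid = manifest$grid, pso = manifest$pso,
                  seed = manifest$seed, smoothing_p = manifest$smoothing_p,
                  fraction = manifest$fraction,
                  replicate_policy = manifest$replicate_policy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(run, file.path(out_dir, "report.csv"))
  sdir <- file.path(out_dir, "splits")
  dir.create(sdir, showWarnings = FALSE)
  for (at in manifest$grid$attributes) {
    best_row <- run$best[run$best$attribute == at, ]
    label <- paste(at, best_row$pre_treatment, best_row$normalization,
                   best_row$svr_type, best_row$kernel, sep = "|")
    write_split(run$records[[label]]$split,
                file.path(sdir, paste0(gsub("[^A-Za-z0-9]+", "_", at),
                                       ".json")))
  }
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(run)
}

#' Serialize / restore a run manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  gen_path <- NULL
  payload <- list(format = "nirsense-manifest/1",
                  generator = if (!is.null(manifest$generator)) {
                    tmp <- tempfile(fileext = ".json")
                    on.exit(unlink(tmp), add = TRUE)
                    write_generator_config(manifest$generator, tmp)
                    jsonlite::fromJSON(tmp, simplifyVector = FALSE)
                  },
                  spectra_csv = manifest$spectra_csv,
                  sensory_csv = manifest$sensory_csv,
                  grid = unclass(manifest$grid),
                  pso = unclass(manifest$pso),
                  seed = manifest$seed,
                  smoothing_p = manifest$smoothing_p,
                  fraction = manifest$fraction,
                  replicate_policy = manifest$replicate_policy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(x$format, "nirsense-manifest/1")) {
    stop("not a nirsense manifest: ", path, call. = FALSE)
  }
  gen <- NULL
  if (!is.null(x$generator)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(x$generator, tmp, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    gen <- read_generator_config(tmp)
  }
  pso <- do.call(pso_config, x$pso[setdiff(names(x$pso), character(0))])
  run_manifest(generator = gen, spectra_csv = x$spectra_csv,
               sensory_csv = x$sensory_csv,
               grid = do.call(grid_spec, as.list(x$grid)),
               pso = pso, seed = x$seed, smoothing_p = x$smoothing_p,
               fraction = x$fraction, replicate_policy = x$replicate_policy)
}
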