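#' Write / read a spectra set as wide CSV
#'
#' Wide layout: `sample_id`, `replicate`, then one column per wavenumber
#' labeled with its cm^-1 value. Comma separator, `.` decimal, UTF-8,
#' mandatory header.
#'
#' @param x A [spectra_set()].
#' @param path File path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   a validated [spectra_set()].
#' @export
write_spectra <- function(x, path) {
  validate_spectra_set(x)
  df <- data.frame(sample_id = x$sample_ids, replicate = x$replicate_ids,
                   stringsAsFactors = FALSE, check.names = FALSE)
  ab <- as.data.frame(x$absorbance)
  names(ab) <- sprintf("%.17g", x$wavenumbers)  # numeric labels round-trip
  df <- cbind(df, ab)
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  need <- c("sample_id", "replicate")
  if (!all(need %in% names(df)[1:2])) {
    stop("spectra CSV must start with columns 'sample_id', 'replicate'",
         call. = FALSE)
  }
  wn_labels <- setdiff(names(df), need)
  wn <- suppressWarnings(as.numeric(wn_labels))
  if (anyNA(wn)) {
    stop("non-numeric wavenumber column label(s): ",
         paste(wn_labels[is.na(wn)], collapse = ", "), call. = FALSE)
  }
  ord <- order(wn)
  A <- as.matrix(df[, wn_labels[ord], drop = FALSE])
  if (!is.numeric(A)) {
    bad <- wn_labels[ord][!vapply(df[, wn_labels[ord], drop = FALSE],
                                  is.numeric, logical(1))]
    stop("non-numeric absorbance in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(A)) {
    bad <- which(is.na(A), arr.ind = TRUE)[1, ]
    stop(sprintf("missing absorbance at row %d (sample %s), column %s cm-1",
                 bad[1], df$sample_id[bad[1]], wn[ord][bad[2]]), call. = FALSE)
  }
  dimnames(A) <- NULL
  spectra_set(wn[ord], A, df$sample_id, df$replicate)
}

#' Write / read a sensory score table as CSV
#'
#' `sample_id` column followed by one column per attribute.
#'
#' @param x A [sensory_table()].
#' @param path File path.
#' @param strict On read, treat scores outside `[1, 9]` as an error
#'   (`TRUE`, default) or a warning (`FALSE`).
#' @return `write_sensory` returns `path` invisibly; `read_sensory` returns
#'   a validated [sensory_table()].
#' @export
write_sensory <- function(x, path) {
  stopifnot(inherits(x, "sensory_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sensory
#' @export
read_sensory <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if (names(df)[1] != "sample_id") {
    stop("sensory CSV must start with a 'sample_id' column", call. = FALSE)
  }
  sensory_table(df$sample_id, df[, -1, drop = FALSE], strict = strict)
}

#' Pair spectra with sensory scores
#'
#' Matches records by `sample_id` and returns one X row per Y row under the
#' chosen replicate policy: `"mean"` (default) averages the replicate
#' spectra of each sample; `"keep"` retains every replicate and repeats the
#' sample's sensory row for each.
#'
#' @param spectra A [spectra_set()].
#' @param sensory A [sensory_table()].
#' @param replicate_policy `"mean"` or `"keep"`.
#' @return A list of class `paired_dataset` with elements `X` (matrix, row
#'   names = sample ids), `sensory` (matching [sensory_table()] rows),
#'   `wavenumbers`, `sample_ids`, `replicate_policy`.
#' @export
align_spectra_sensory <- function(spectra, sensory,
                                  replicate_policy = c("mean", "keep")) {
  replicate_policy <- match.arg(replicate_policy)
  validate_spectra_set(spectra)
  stopifnot(inherits(sensory, "sensory_table"))
  ids <- unique(spectra$sample_ids)
  common <- ids[ids %in% sensory$sample_id]
  if (length(common) == 0) {
    stop("no sample_id is shared between spectra and sensory table",
         call. = FALSE)
  }
  sens <- sensory[match(common, sensory$sample_id), , drop = FALSE]
  if (replicate_policy == "mean") {
    X <- t(vapply(common, function(s) {
      colMeans(spectra$absorbance[spectra$sample_ids == s, , drop = FALSE])
    }, numeric(length(spectra$wavenumbers))))
    rownames(X) <- common
    out_ids <- common
  } else {
    keep <- spectra$sample_ids %in% common
    ord <- order(match(spectra$sample_ids[keep], common),
                 spectra$replicate_ids[keep])
    X <- spectra$absorbance[keep, , drop = FALSE][ord, , drop = FALSE]
    out_ids <- spectra$sample_ids[keep][ord]
    rownames(X) <- paste(out_ids, spectra$replicate_ids[keep][ord], sep = "_r")
    sens <- sens[match(out_ids, sens$sample_id), , drop = FALSE]
  }
  structure(list(X = X, sensory = sens, wavenumbers = spectra$wavenumbers,
                 sample_ids = out_ids, replicate_policy = replicate_policy),
            class = "paired_dataset")
}

#' Serialize / restore a generator configuration as JSON
#'
#' The round trip is bit-exact: numbers are written at full precision and
#' the restored object passes through the same validation as
#' [generator_config()].
#'
#' @param config A [generator_config()].
#' @param path JSON file path.
#' @return `write_generator_config` returns `path` invisibly;
#'   `read_generator_config` returns a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  W <- config$attribute_weights
  payload <- list(
    format = "nirsense-generator-config/1",
    n_samples = config$n_samples,
    n_replicates = config$n_replicates,
    wavenumber_start = config$wavenumber_start,
    wavenumber_stop = config$wavenumber_stop,
    wavenumber_step = config$wavenumber_step,
    bands = config$bands,
    baseline = config$baseline,
    scatter_gain_sd = config$scatter_gain_sd,
    scatter_offset_sd = config$scatter_offset_sd,
    noise_sd = config$noise_sd,
    dirichlet_mean = as.list(config$dirichlet_mean),
    dirichlet_concentration = config$dirichlet_concentration,
    attribute_targets = config$attribute_targets,
    attribute_weights = cbind(data.frame(attribute = rownames(W),
                                         stringsAsFactors = FALSE),
                              as.data.frame(W)),
    nonlinearity = config$nonlinearity,
    sensory_noise_frac = config$sensory_noise_frac,
    seed = config$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!identical(x$format, "nirsense-generator-config/1")) {
    stop("not a nirsense generator config file: ", path, call. = FALSE)
  }
  wdf <- x$attribute_weights
  W <- as.matrix(wdf[, setdiff(names(wdf), "attribute"), drop = FALSE])
  rownames(W) <- wdf$attribute
  generator_config(
    n_samples = x$n_samples, n_replicates = x$n_replicates,
    wavenumber_start = x$wavenumber_start,
    wavenumber_stop = x$wavenumber_stop,
    wavenumber_step = x$wavenumber_step,
    bands = x$bands, baseline = x$baseline,
    scatter_gain_sd = x$scatter_gain_sd,
    scatter_offset_sd = x$scatter_offset_sd,
    noise_sd = x$noise_sd,
    dirichlet_mean = unlist(x$dirichlet_mean),
    dirichlet_concentration = x$dirichlet_concentration,
    attribute_targets = x$attribute_targets,
    attribute_weights = W,
    nonlinearity = x$nonlinearity,
    sensory_noise_frac = x$sensory_noise_frac,
    seed = x$seed)
}

#' Save / load a fitted calibration model bundle
#'
#' The bundle (R serialization, format-tagged) contains the regression fit
#' together with the pre-treatment and normalization state captured on the
#' calibration set, so prediction-time application is bit-reproducible.
#'
#' @param model A fitted model (e.g. from [fit_svr()], [fit_pls()] or a
#'   pipeline `calibration_model`).
#' @param path File path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "nirsense-model/1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "nirsense-model/1")) {
    stop("not a nirsense model bundle: ", path, call. = FALSE)
  }
  x$model
}

#' Serialize / restore a calibration/prediction split as JSON
#' @param split A `split_result` (see [spxy()]).
#' @param path JSON file path.
#' @return `write_split` returns `path` invisibly; `read_split` the split.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  jsonlite::write_json(list(format = "nirsense-split/1",
                            calibration_idx = split$calibration_idx,
                            prediction_idx = split$prediction_idx,
                            fraction = split$fraction),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!identical(x$format, "nirsense-split/1")) {
    stop("not a nirsense split file: ", path, call. = FALSE)
  }
  structure(list(calibration_idx = as.integer(x$calibration_idx),
                 prediction_idx = as.integer(x$prediction_idx),
                 fraction = x$fraction),
            class = "split_result")
}
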