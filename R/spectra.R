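#' Canonical sensory attribute names
#'
#' The ten descriptors scored by the trained panel on the 1--9 intensity
#' scale: odor, boar-taint descriptors (androsterone, scatol), appearance
#' (lean and fat color), oral texture (hardness, juiciness, chewiness) and
#' flavor (intensity, persistence).
#'
#' @return Character vector of length ten.
#' @export
sensory_attributes <- function() {
  c("Odor", "Andros", "Scatol", "Lean color", "Fat color",
    "Hardness", "Juiciness", "Chewiness", "Flavor intensity",
    "Flavor persistence")
}

#' Construct a spectra set
#'
#' A `spectra_set` holds one absorbance matrix (rows are sample-replicate
#' records, columns are wavenumber channels) together with its wavenumber
#' axis and sample/replicate identity. It is the X block at every pipeline
#' stage.
#'
#' @param wavenumbers Strictly increasing numeric vector, cm^-1.
#' @param absorbance Numeric matrix, one row per sample-replicate record,
#'   `length(wavenumbers)` columns.
#' @param sample_ids Character or integer vector, one per row.
#' @param replicate_ids Integer vector, one per row.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids,
                        replicate_ids = rep(1L, nrow(absorbance)),
                        validate = TRUE) {
  absorbance <- as.matrix(absorbance)
  obj <- structure(
    list(wavenumbers = as.numeric(wavenumbers),
         absorbance = absorbance,
         sample_ids = as.character(sample_ids),
         replicate_ids = as.integer(replicate_ids)),
    class = "spectra_set")
  if (validate) validate_spectra_set(obj)
  obj
}

validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  w <- x$wavenumbers
  if (length(w) < 1 || any(diff(w) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  n <- nrow(x$absorbance)
  if (ncol(x$absorbance) != length(w)) {
    stop(sprintf("absorbance has %d columns but %d wavenumbers",
                 ncol(x$absorbance), length(w)), call. = FALSE)
  }
  if (length(x$sample_ids) != n || length(x$replicate_ids) != n) {
    stop("sample_ids/replicate_ids must match the number of spectra rows",
         call. = FALSE)
  }
  if (anyNA(x$absorbance) || any(!is.finite(x$absorbance))) {
    bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite absorbance at row %d (sample %s), column %d (%g cm-1)",
                 bad[1], x$sample_ids[bad[1]], bad[2], w[bad[2]]), call. = FALSE)
  }
  key <- paste(x$sample_ids, x$replicate_ids)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (sample, replicate) record: %s",
                 key[anyDuplicated(key)]), call. = FALSE)
  }
  reps <- table(x$sample_ids)
  if (length(unique(as.integer(reps))) > 1) {
    stop("every sample must have the same number of replicate spectra",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra (%d samples x %d replicates), %d channels, %g-%g cm-1\n",
              nrow(x$absorbance), length(unique(x$sample_ids)),
              as.integer(table(x$sample_ids)[1]), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

# Row subset preserving metadata. Internal.
spectra_subset <- function(x, rows) {
  spectra_set(x$wavenumbers, x$absorbance[rows, , drop = FALSE],
              x$sample_ids[rows], x$replicate_ids[rows], validate = FALSE)
}

# Replace the absorbance matrix, keeping axis/identity. Internal.
spectra_with <- function(x, absorbance, wavenumbers = x$wavenumbers) {
  spectra_set(wavenumbers, absorbance, x$sample_ids, x$replicate_ids,
              validate = FALSE)
}

#' Construct a sensory score table
#'
#' One row per sample; ten attribute columns on the 1--9 panel scale.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param scores Data frame or matrix of scores, one column per attribute.
#' @param strict Error (rather than warn) on scores outside `[1, 9]`.
#' @return An object of class `sensory_table` (a data.frame with a
#'   `sample_id` column followed by the attribute columns).
#' @export
sensory_table <- function(sample_ids, scores, strict = TRUE) {
  scores <- as.data.frame(scores, check.names = FALSE)
  unknown <- setdiff(names(scores), sensory_attributes())
  if (length(unknown)) {
    stop(sprintf("unknown sensory attribute(s): %s; valid names are: %s",
                 paste(unknown, collapse = ", "),
                 paste(sensory_attributes(), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample_id in sensory table", call. = FALSE)
  }
  vals <- as.matrix(scores)
  if (anyNA(vals)) stop("missing sensory scores are not allowed", call. = FALSE)
  out_of_range <- vals < 1 | vals > 9
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)[1, ]
    msg <- sprintf("score %g for sample %s, attribute '%s' outside the 1-9 scale",
                   vals[bad[1], bad[2]], sample_ids[bad[1]],
                   names(scores)[bad[2]])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out <- cbind(data.frame(sample_id = as.character(sample_ids),
                          stringsAsFactors = FALSE),
               scores)
  class(out) <- c("sensory_table", "data.frame")
  out
}

#' @export
print.sensory_table <- function(x, ...) {
  cat(sprintf("<sensory_table> %d samples x %d attributes\n",
              nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Extract the score matrix of a sensory table
#' @param x A [sensory_table()].
#' @return Numeric matrix (samples x attributes) with sample-id row names.
#' @export
sensory_matrix <- function(x) {
  stopifnot(inherits(x, "sensory_table"))
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}
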