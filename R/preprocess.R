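#' Available preprocessing methods
#' @return Character vector `c("none", "snv", "mean_center", "autoscale")`.
#' @export
preprocess_methods <- function() c("none", "snv", "mean_center", "autoscale")

#' Standard normal variate transform
#'
#' Per-spectrum (row-wise) centering and scaling to unit standard deviation:
#' `(x - mean(x)) / sd(x)` with the n-1 denominator. Removes per-spectrum
#' additive offsets and multiplicative scatter; invariant under
#' `a * x + c` for any `a > 0`, and idempotent.
#'
#' @param x Numeric vector (one spectrum) or matrix (spectra in rows).
#' @param sample_ids Optional ids used in the zero-variance error message.
#' @return Transformed vector or matrix of the same shape.
#' @export
snv_transform <- function(x, sample_ids = NULL) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("snv requires at least 2 wavelengths", call. = FALSE)
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    if (any(sdv == 0)) {
      bad <- which(sdv == 0)
      nm <- if (!is.null(sample_ids)) sample_ids[bad]
        else if (!is.null(rownames(x))) rownames(x)[bad] else as.character(bad)
      stop("zero-variance (flat) spectrum, cannot apply snv: sample(s) ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    (x - mu) / sdv
  } else {
    drop(snv_transform(matrix(x, nrow = 1), sample_ids = sample_ids))
  }
}

#' Fit a preprocessing model on calibration data
#'
#' Learns the statistics a method needs from the calibration set only:
#' per-wavelength means (`mean_center`, `autoscale`) and per-wavelength
#' standard deviations with the n-1 denominator (`autoscale`). `none` and
#' `snv` store no statistics (snv is purely per-spectrum). The frozen model
#' is then applied unchanged to validation or new data, so no validation
#' information leaks into the statistics.
#'
#' @param method One of [preprocess_methods()].
#' @param calibration A nonempty [spectra_set()].
#' @return A `preprocess_model` with fields `method`, `wavelengths`, and
#'   (when relevant) `column_means`, `column_sds`.
#' @export
fit_preprocess <- function(method, calibration) {
  method <- match.arg(method, preprocess_methods())
  validate_spectra_set(calibration)
  if (n_samples(calibration) == 0)
    stop("cannot fit preprocessing on an empty calibration set", call. = FALSE)
  model <- list(method = method, wavelengths = calibration$wavelengths,
                column_means = NULL, column_sds = NULL)
  if (method %in% c("mean_center", "autoscale"))
    model$column_means <- colMeans(calibration$absorbance)
  if (method == "autoscale") {
    sds <- apply(calibration$absorbance, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- calibration$wavelengths[sds == 0]
      stop("zero-variance wavelength column(s) under autoscale: ",
           paste(format_wavelength(bad), collapse = ", "), " nm", call. = FALSE)
    }
    model$column_sds <- sds
  }
  structure(model, class = "preprocess_model")
}

#' Apply a fitted preprocessing model
#'
#' `none` returns the data unchanged; `snv` applies [snv_transform()] row
#' by row; `mean_center` subtracts the stored calibration column means;
#' `autoscale` subtracts the stored means and divides by the stored
#' standard deviations. Applying `mean_center`/`autoscale` twice subtracts
#' the stored statistics twice (deliberately not idempotent: the model is a
#' fixed affine map).
#'
#' @param model A `preprocess_model` from [fit_preprocess()].
#' @param dataset A [spectra_set()] on the model's training grid.
#' @return A transformed [spectra_set()].
#' @export
apply_preprocess <- function(model, dataset) {
  stopifnot(inherits(model, "preprocess_model"))
  validate_spectra_set(dataset)
  if (!isTRUE(all.equal(dataset$wavelengths, model$wavelengths)))
    stop("wavelength grid mismatch between preprocess model (",
         length(model$wavelengths), " points) and dataset (",
         length(dataset$wavelengths), " points)", call. = FALSE)
  mat <- dataset$absorbance
  mat <- switch(model$method,
    none = mat,
    snv = if (nrow(mat)) snv_transform(mat, dataset$sample_ids) else mat,
    mean_center = sweep(mat, 2, model$column_means, "-"),
    autoscale = sweep(sweep(mat, 2, model$column_means, "-"),
                      2, model$column_sds, "/"))
  out <- dataset
  out$absorbance <- mat
  dimnames(out$absorbance) <- dimnames(dataset$absorbance)
  out
}
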