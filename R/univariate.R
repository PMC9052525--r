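#' Extract single-wavelength optical density
#'
#' Returns the absorbance column at one wavelength (450 nm by default, the
#' TMB product peak a plate reader reports), in sample order.
#'
#' @param dataset A [spectra_set()].
#' @param wavelength Wavelength (nm); must lie exactly on the grid.
#' @return Named numeric vector of OD values (names = sample ids).
#' @export
extract_od <- function(dataset, wavelength = 450) {
  validate_spectra_set(dataset)
  idx <- which(dataset$wavelengths == wavelength)
  if (length(idx) != 1) {
    nearest <- dataset$wavelengths[order(abs(dataset$wavelengths - wavelength))]
    stop("wavelength ", wavelength, " nm is not on the grid; nearest grid points: ",
         paste(utils::head(nearest, 2), collapse = ", "), " nm", call. = FALSE)
  }
  stats::setNames(dataset$absorbance[, idx], dataset$sample_ids)
}

#' Learn the two OD class boundaries
#'
#' The univariate rule uses the empirical class extremes: the normal/mild
#' boundary `t_low` is the maximum OD among normal samples and the
#' mild/severe boundary `t_high` is the maximum OD among mild samples —
#' i.e. each class's maximum is taken as the next class's minimum, the way
#' the OD bar chart of a graded assay is read.
#'
#' @param od_values Numeric OD vector.
#' @param labels Class labels, same length (see [class_levels()]).
#' @param wavelength Wavelength the ODs came from (stored for reporting).
#' @return A `threshold_model` with fields `wavelength`, `t_low`, `t_high`.
#' @export
fit_thresholds <- function(od_values, labels, wavelength = 450) {
  labels <- as_class_label(labels)
  if (length(od_values) != length(labels))
    stop("od_values and labels differ in length", call. = FALSE)
  counts <- table(labels)
  if (any(counts == 0))
    stop("empty class(es): ", paste(names(counts)[counts == 0], collapse = ", "),
         call. = FALSE)
  t_low <- max(od_values[labels == "normal"])
  t_high <- max(od_values[labels == "mild"])
  if (t_low >= t_high)
    stop("non-increasing boundaries: max normal OD (", signif(t_low, 6),
         ") >= max mild OD (", signif(t_high, 6), ")", call. = FALSE)
  structure(list(wavelength = wavelength, t_low = t_low, t_high = t_high),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model> OD(", x$wavelength, " nm): normal < ",
      signif(x$t_low, 4), " <= mild < ", signif(x$t_high, 4),
      " <= severe\n", sep = "")
  invisible(x)
}

#' Classify OD values with a threshold model
#'
#' `normal` if `od < t_low`; `mild` if `t_low <= od < t_high`; `severe` if
#' `od >= t_high`. A value exactly on a boundary goes to the
#' higher-severity class: the boundary is the shared extreme of two
#' adjacent classes, and assigning upward is the conservative clinical
#' choice for a resorption screen.
#'
#' @param od Numeric OD value(s), finite.
#' @param model A `threshold_model`.
#' @return Factor of class labels (levels [class_levels()]).
#' @export
classify_od <- function(od, model) {
  stopifnot(inherits(model, "threshold_model"))
  if (!all(is.finite(od))) stop("non-finite OD value(s)", call. = FALSE)
  out <- ifelse(od < model$t_low, "normal",
                ifelse(od < model$t_high, "mild", "severe"))
  as_class_label(out)
}

#' Train the univariate OD classifier on a calibration set
#'
#' Convenience wrapper: [extract_od()] then [fit_thresholds()].
#'
#' @param calibration Labeled [spectra_set()].
#' @param wavelength Wavelength (nm), default 450.
#' @return A `threshold_model`.
#' @export
univariate_train <- function(calibration, wavelength = 450) {
  if (is.null(calibration$labels))
    stop("calibration set is unlabeled", call. = FALSE)
  fit_thresholds(extract_od(calibration, wavelength), calibration$labels,
                 wavelength = wavelength)
}

#' Predict classes with a univariate threshold model
#'
#' @param model A `threshold_model`.
#' @param dataset A [spectra_set()] whose grid contains the model wavelength.
#' @return Factor of predicted labels, named by sample id.
#' @export
univariate_predict <- function(model, dataset) {
  od <- extract_od(dataset, model$wavelength)
  stats::setNames(classify_od(od, model), dataset$sample_ids)
}
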