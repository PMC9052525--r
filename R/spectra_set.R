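#' Severity class levels
#'
#' The three root-resorption severity classes, in increasing ordinal rank
#' (normal < mild < severe). All labeled data in the package uses this closed
#' set and this order; dummy coding and confusion matrices follow it.
#'
#' @return Character vector `c("normal", "mild", "severe")`.
#' @export
class_levels <- function() c("normal", "mild", "severe")

#' Coerce labels to the severity factor
#'
#' @param x Character vector or factor of class labels.
#' @return Factor with levels `class_levels()`.
#' @export
as_class_label <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% class_levels())
  if (any(bad)) {
    stop("unknown class label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (row ", paste(which(bad), collapse = ", "),
         "); expected one of ", paste(class_levels(), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = class_levels())
}

#' Labeled spectral dataset
#'
#' Container for a set of absorbance spectra sharing one wavelength grid:
#' a samples-by-wavelengths matrix plus sample identifiers and (optionally)
#' severity labels. This is the data model every stage of the pipeline
#' consumes.
#'
#' @param absorbance Numeric matrix, samples in rows, wavelengths in columns
#'   (absorbance units).
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm),
#'   one per column.
#' @param sample_ids Unique character identifiers, one per row.
#' @param labels Optional class labels (see [class_levels()]); `NULL` for
#'   unlabeled prediction input.
#' @return An object of class `spectra_set` with elements `absorbance`,
#'   `wavelengths`, `sample_ids`, `labels`.
#' @export
spectra_set <- function(absorbance, wavelengths, sample_ids, labels = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  sample_ids <- as.character(sample_ids)
  if (!is.null(labels)) labels <- as_class_label(labels)
  obj <- structure(
    list(absorbance = absorbance, wavelengths = wavelengths,
         sample_ids = sample_ids, labels = labels),
    class = "spectra_set")
  validate_spectra_set(obj)
  dimnames(obj$absorbance) <- list(sample_ids, format_wavelength(wavelengths))
  obj
}

format_wavelength <- function(w) {
  # integer grids print as integers so CSV headers round-trip
  ifelse(w == round(w), sprintf("%d", as.integer(round(w))), sprintf("%.6g", w))
}

validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  n <- nrow(x$absorbance)
  p <- ncol(x$absorbance)
  if (length(x$wavelengths) != p)
    stop("wavelength grid length (", length(x$wavelengths),
         ") does not match matrix columns (", p, ")", call. = FALSE)
  if (p >= 2 && any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (length(x$sample_ids) != n)
    stop("sample_ids length (", length(x$sample_ids),
         ") does not match matrix rows (", n, ")", call. = FALSE)
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(x$labels) && length(x$labels) != n)
    stop("labels length (", length(x$labels),
         ") does not match matrix rows (", n, ")", call. = FALSE)
  if (n > 0 && p > 0 && !all(is.finite(x$absorbance))) {
    bad <- which(!apply(is.finite(x$absorbance), 1, all))
    stop("non-finite absorbance values in sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " wavelengths", sep = "")
  if (ncol(x$absorbance) > 0)
    cat(" (", min(x$wavelengths), "-", max(x$wavelengths), " nm)", sep = "")
  cat("\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else cat("  unlabeled\n")
  invisible(x)
}

#' Number of samples in a spectra_set
#' @param x A `spectra_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' Subset a spectra_set by sample index
#'
#' @param x A `spectra_set`.
#' @param idx Integer or logical row index.
#' @return A `spectra_set` with the selected samples, grid unchanged.
#' @export
subset_samples <- function(x, idx) {
  spectra_set(x$absorbance[idx, , drop = FALSE], x$wavelengths,
              x$sample_ids[idx],
              if (is.null(x$labels)) NULL else x$labels[idx])
}

#' Combine spectra_sets sharing a grid
#' @param ... `spectra_set` objects on identical wavelength grids.
#' @return A single combined `spectra_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  grid <- sets[[1]]$wavelengths
  for (s in sets) {
    if (!isTRUE(all.equal(s$wavelengths, grid)))
      stop("cannot bind spectra sets on different wavelength grids", call. = FALSE)
  }
  labs <- lapply(sets, `[[`, "labels")
  has_lab <- !vapply(labs, is.null, logical(1))
  if (any(has_lab) && !all(has_lab))
    stop("cannot mix labeled and unlabeled spectra sets", call. = FALSE)
  spectra_set(
    do.call(rbind, lapply(sets, `[[`, "absorbance")),
    grid,
    unlist(lapply(sets, `[[`, "sample_ids")),
    if (all(has_lab)) unlist(lapply(lapply(sets, `[[`, "labels"), as.character))
    else NULL)
}
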