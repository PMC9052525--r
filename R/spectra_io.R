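#' Read a labeled spectral dataset from CSV
#'
#' Reads the package's wide CSV dialect: columns `sample_id`, `label`, then
#' one column per wavelength named by its nm value (`"300"` ... `"550"`).
#' The `label` column may be empty for unlabeled data. This layout mirrors a
#' microplate-reader spectral-scan export.
#'
#' @param path Path to a CSV file.
#' @return A [spectra_set()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nfields <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(unique(nfields)) > 1)
    stop("ragged rows in ", path, ": lines have ",
         paste(unique(nfields), collapse = ", "), " fields", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 3 || names(df)[1] != "sample_id" || names(df)[2] != "label")
    stop("expected header starting with sample_id,label followed by wavelength columns",
         call. = FALSE)
  wl_names <- names(df)[-(1:2)]
  wavelengths <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wavelengths))
    stop("non-numeric wavelength column header(s): ",
         paste(wl_names[is.na(wavelengths)], collapse = ", "), call. = FALSE)
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("wavelength column headers are not strictly increasing", call. = FALSE)
  n <- nrow(df)
  mat <- matrix(NA_real_, n, length(wavelengths))
  if (n > 0) {
    vals <- suppressWarnings(vapply(df[-(1:2)], as.numeric, numeric(n)))
    mat <- matrix(as.numeric(vals), nrow = n)
    if (anyNA(mat)) {
      bad <- which(apply(is.na(mat), 1, any))
      stop("non-numeric or missing absorbance in row(s): ",
           paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  labels_raw <- df$label
  labels <- if (n == 0 || all(is.na(labels_raw) | labels_raw == "")) NULL else {
    labels_raw[labels_raw == ""] <- NA_character_
    bad <- !is.na(labels_raw) & !(labels_raw %in% class_levels())
    if (any(bad))
      stop("unknown class label(s) in ", path, ": ",
           paste(sprintf("'%s' (sample %s)", labels_raw[bad], df$sample_id[bad]),
                 collapse = ", "), call. = FALSE)
    labels_raw
  }
  spectra_set(mat, wavelengths, df$sample_id, labels)
}

#' Write a spectral dataset to CSV
#'
#' Inverse of [read_spectra()]. Absorbances are written with 12 significant
#' digits so that a write/read round trip is exact to well below 1e-9 and a
#' second write is byte-identical to the first.
#'
#' @param dataset A [spectra_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(dataset, path) {
  validate_spectra_set(dataset)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  header <- c("sample_id", "label", format_wavelength(dataset$wavelengths))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  n <- n_samples(dataset)
  if (n > 0) {
    labs <- if (is.null(dataset$labels)) rep("", n) else {
      l <- as.character(dataset$labels); l[is.na(l)] <- ""; l
    }
    vals <- matrix(sprintf("%.12g", dataset$absorbance), nrow = n)
    lines <- paste(dataset$sample_ids, labs,
                   apply(vals, 1, paste, collapse = ","), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}
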