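#' Published reference tables of the motivating study
#'
#' Loads the transcribed printed result tables of the DSPP/ELISA
#' root-resorption study that motivates this package: the univariate
#' confusion matrix, its printed truth table and metrics, and the PLS-DA
#' calibration/validation confusion matrices and printed metrics for each
#' preprocessing method. These serve as worked-example fixtures: feeding
#' the printed confusion matrices through [truth_table()] and
#' [class_metrics()] reproduces the printed metric tables.
#'
#' Confusion matrices are returned as [as_confusion_matrix()] objects
#' (rows predicted, columns actual).
#'
#' @return Nested list with elements `univariate` (`confusion`,
#'   `printed_truth_table`, `printed_metrics`) and `plsda` (one element
#'   per preprocessing method with `confusion$calibration`,
#'   `confusion$validation`, `printed_metrics`).
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.json", package = "odspectra",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$univariate$confusion <- as_confusion_matrix(raw$univariate$confusion)
  for (m in names(raw$plsda)) {
    raw$plsda[[m]]$confusion$calibration <-
      as_confusion_matrix(raw$plsda[[m]]$confusion$calibration)
    raw$plsda[[m]]$confusion$validation <-
      as_confusion_matrix(raw$plsda[[m]]$confusion$validation)
  }
  raw
}
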