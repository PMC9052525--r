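#' Stratified calibration/validation split
#'
#' Seeded random partition at `calibration_fraction` (default 7:3, the
#' ratio used for small assay datasets). When stratified, per-class
#' calibration counts start from round-half-up of `fraction * class n` and
#' are adjusted by largest remainder so the total equals
#' round-half-up of `fraction * n`; the two subsets are disjoint and
#' exhaustive, and the same seed always yields the same partition.
#'
#' @param dataset Labeled [spectra_set()] (labels required when
#'   `stratified`).
#' @param calibration_fraction Fraction in (0, 1), default 0.7.
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed (mandatory).
#' @return List with `calibration` and `validation` [spectra_set()]s and a
#'   `membership` data frame (`sample_id`, `domain`).
#' @export
split_calibration_validation <- function(dataset, calibration_fraction = 0.7,
                                         stratified = TRUE, seed) {
  validate_spectra_set(dataset)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop("calibration_fraction must be in (0, 1)", call. = FALSE)
  n <- n_samples(dataset)
  total_cal <- round_half_up(calibration_fraction * n)
  cal_idx <- run_seeded(seed, {
    if (stratified) {
      if (is.null(dataset$labels)) stop("stratified split requires labels", call. = FALSE)
      counts <- table(dataset$labels)
      if (any(counts < 2))
        stop("class(es) too small to stratify (need >= 2 samples): ",
             paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
      alloc <- allocate_counts(calibration_fraction, as.integer(counts), total_cal)
      unlist(lapply(seq_along(levels(dataset$labels)), function(k) {
        idx <- which(as.integer(dataset$labels) == k)
        sort(sample(idx, alloc[k]))
      }))
    } else sort(sample(seq_len(n), total_cal))
  })
  cal_idx <- sort(cal_idx)
  val_idx <- setdiff(seq_len(n), cal_idx)
  membership <- data.frame(
    sample_id = dataset$sample_ids,
    domain = ifelse(seq_len(n) %in% cal_idx, "calibration", "validation"),
    stringsAsFactors = FALSE)
  list(calibration = subset_samples(dataset, cal_idx),
       validation = subset_samples(dataset, val_idx),
       membership = membership)
}

round_half_up <- function(x) floor(x + 0.5)

# Per-class counts: round-half-up per class, then largest-remainder
# adjustment toward the required total.
allocate_counts <- function(fraction, class_n, total) {
  desired <- fraction * class_n
  alloc <- round_half_up(desired)
  alloc <- pmin(pmax(alloc, 0L), class_n)
  while (sum(alloc) > total) {
    over <- alloc - desired
    over[alloc <= 0] <- -Inf
    k <- which.max(over)
    alloc[k] <- alloc[k] - 1L
  }
  while (sum(alloc) < total) {
    under <- desired - alloc
    under[alloc >= class_n] <- -Inf
    k <- which.max(under)
    alloc[k] <- alloc[k] + 1L
  }
  as.integer(alloc)
}

#' Build a 3x3 confusion matrix
#'
#' Rows are predicted classes and columns actual classes, both in class
#' order (normal, mild, severe) — the orientation the study tables use.
#'
#' @param actual,predicted Equal-length class label vectors.
#' @return Integer 3x3 matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(actual, predicted) {
  actual <- as_class_label(actual); predicted <- as_class_label(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  cm <- unclass(table(predicted = predicted, actual = actual))
  structure(matrix(as.integer(cm), 3, 3,
                   dimnames = list(predicted = class_levels(),
                                   actual = class_levels())),
            class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain matrix to a confusion_matrix
#' @param m 3x3 numeric matrix, rows predicted, columns actual.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3, 3))) stop("expected a 3x3 matrix", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers", call. = FALSE)
  structure(matrix(as.integer(m), 3, 3,
                   dimnames = list(predicted = class_levels(),
                                   actual = class_levels())),
            class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest truth table from a confusion matrix
#'
#' Standard one-vs-rest decomposition: for class k,
#' `TP = cm[k, k]`, `FP = row k sum - TP` (predicted k but another class),
#' `FN = column k sum - TP` (class k predicted otherwise),
#' `TN = total - TP - FP - FN`.
#'
#' @param cm A `confusion_matrix` (or coercible 3x3 matrix).
#' @return A `truth_table` data frame with columns `class`, `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
truth_table <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  tn <- total - tp - fp - fn
  structure(data.frame(class = class_levels(), TP = as.integer(tp),
                       FP = as.integer(fp), TN = as.integer(tn),
                       FN = as.integer(fn), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}

#' Build a truth table directly from printed counts
#' @param TP,FP,TN,FN Integer vectors of length 3, class order.
#' @return A `truth_table`.
#' @export
truth_table_from_counts <- function(TP, FP, TN, FN) {
  stopifnot(length(TP) == 3, length(FP) == 3, length(TN) == 3, length(FN) == 3)
  tot <- TP + FP + TN + FN
  if (length(unique(tot)) != 1)
    stop("TP+FP+TN+FN must be equal across classes", call. = FALSE)
  structure(data.frame(class = class_levels(), TP = as.integer(TP),
                       FP = as.integer(FP), TN = as.integer(TN),
                       FN = as.integer(FN), row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}

#' Classification metrics from a truth table
#'
#' Per class: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)`. Overall:
#' `macro_accuracy` (mean of the three per-class accuracies — the variant
#' reported as "overall accuracy" in graded-assay tables) and
#' `micro_accuracy` (correctly classified / total).
#'
#' Degenerate-ratio conventions: precision with `TP+FP = 0` is reported as
#' 1.0 (no positive call was made, so none was wrong — and the convention
#' a class absent from a small validation set needs); sensitivity or
#' specificity with a zero denominator is `NA`. Every applied convention
#' is listed in the `flags` attribute.
#'
#' @param tt A `truth_table` (or a `confusion_matrix`, converted first).
#' @return A `metrics_report`: list with `per_class` data frame
#'   (`class`, `sensitivity`, `specificity`, `precision`, `accuracy`),
#'   `macro_accuracy`, `micro_accuracy`, `total`, and `flags`.
#' @export
class_metrics <- function(tt) {
  if (inherits(tt, "confusion_matrix") ||
      (is.matrix(tt) && all(dim(tt) == c(3, 3)))) tt <- truth_table(tt)
  stopifnot(inherits(tt, "truth_table"))
  flags <- character(0)
  ratio <- function(num, den, kind, zero_value) {
    out <- numeric(length(num))
    for (i in seq_along(num)) {
      if (den[i] == 0) {
        out[i] <- zero_value
        flags <<- c(flags, paste0(kind, " 0/0 for class '", tt$class[i],
                                  "' reported as ", zero_value))
      } else out[i] <- num[i] / den[i]
    }
    out
  }
  sens <- ratio(tt$TP, tt$TP + tt$FN, "sensitivity", NA_real_)
  spec <- ratio(tt$TN, tt$TN + tt$FP, "specificity", NA_real_)
  prec <- ratio(tt$TP, tt$TP + tt$FP, "precision", 1.0)
  tot <- tt$TP + tt$FP + tt$TN + tt$FN
  acc <- (tt$TP + tt$TN) / tot
  total <- tot[1]
  structure(list(
    per_class = data.frame(class = tt$class, sensitivity = sens,
                           specificity = spec, precision = prec,
                           accuracy = acc, row.names = NULL,
                           stringsAsFactors = FALSE),
    macro_accuracy = mean(acc),
    micro_accuracy = sum(tt$TP) / total,
    total = as.integer(total),
    flags = flags), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  df[-1] <- lapply(df[-1], round, 2)
  print(df, row.names = FALSE)
  cat(sprintf("macro accuracy %.2f | micro accuracy %.2f | n=%d\n",
              x$macro_accuracy, x$micro_accuracy, x$total))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Render comparative report tables
#'
#' Collects per-method results into two long tables shaped like the
#' study's comparison tables: one of confusion-matrix counts and one of
#' metrics (rounded to 2 decimals, half to even; raw values are kept in
#' the JSON output). Optionally writes `confusions.csv`, `metrics.csv` and
#' `report.json` (full precision) into a directory.
#'
#' @param results Named list (one element per method) of lists with
#'   elements `calibration` and/or `validation`, each a list with
#'   `confusion` (a `confusion_matrix`) and `metrics` (a
#'   `metrics_report`).
#' @param dir Optional output directory (created if needed).
#' @return List with data frames `confusions` and `metrics` (invisibly
#'   also written if `dir` given).
#' @export
render_report <- function(results, dir = NULL) {
  stopifnot(length(results) >= 1, !is.null(names(results)))
  conf_rows <- list(); met_rows <- list()
  for (method in names(results)) {
    for (domain in intersect(c("calibration", "validation"), names(results[[method]]))) {
      res <- results[[method]][[domain]]
      cm <- res$confusion
      df <- as.data.frame(as.table(unclass(cm)), stringsAsFactors = FALSE)
      names(df) <- c("predicted", "actual", "count")
      df <- cbind(method = method, domain = domain, df)
      conf_rows[[length(conf_rows) + 1L]] <- df
      pc <- res$metrics$per_class
      md <- data.frame(method = method, domain = domain, class = pc$class,
                       sensitivity = round(pc$sensitivity, 2),
                       specificity = round(pc$specificity, 2),
                       precision = round(pc$precision, 2),
                       accuracy = round(pc$accuracy, 2),
                       stringsAsFactors = FALSE)
      met_rows[[length(met_rows) + 1L]] <- md
    }
  }
  out <- list(confusions = do.call(rbind, conf_rows),
              metrics = do.call(rbind, met_rows))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$confusions, file.path(dir, "confusions.csv"),
                     row.names = FALSE)
    utils::write.csv(out$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
    raw <- lapply(results, function(m) lapply(m, function(res) list(
      confusion = unclass(res$confusion),
      per_class = res$metrics$per_class,
      macro_accuracy = res$metrics$macro_accuracy,
      micro_accuracy = res$metrics$micro_accuracy,
      flags = res$metrics$flags)))
    jsonlite::write_json(raw, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Evaluate predictions against actual labels
#'
#' Convenience: confusion matrix, truth table and metrics in one call.
#'
#' @param actual,predicted Class label vectors.
#' @return List with `confusion`, `truth_table`, `metrics`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  cm <- confusion_matrix(actual, predicted)
  tt <- truth_table(cm)
  list(confusion = cm, truth_table = tt, metrics = class_metrics(tt))
}
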