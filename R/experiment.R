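#' Experiment configuration
#'
#' Describes a full comparison run: the input spectra (a
#' [synthetic_config()] or a CSV path readable by [read_spectra()]), the
#' calibration/validation split, and the list of classification methods to
#' compare.
#'
#' @param input A `synthetic_config` or a path to a spectra CSV.
#' @param calibration_fraction Split fraction, default 0.7.
#' @param stratified Stratify the split by class, default `TRUE`.
#' @param split_seed Seed for the split (defaults to `seed`).
#' @param methods List of method entries; each entry is a list with
#'   `method` (`"univariate"` or `"plsda"`) and, for plsda, `preprocess`
#'   and optional `n_components`. Default: univariate plus PLS-DA with
#'   each of the four preprocessing options.
#' @param seed Experiment seed (mandatory).
#' @param output_dir Optional directory for artifacts; see
#'   [run_experiment()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(input, calibration_fraction = 0.7,
                              stratified = TRUE, split_seed = NULL,
                              methods = default_methods(), seed,
                              output_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (!inherits(input, "synthetic_config") &&
      !(is.character(input) && length(input) == 1))
    stop("input must be a synthetic_config or a CSV path", call. = FALSE)
  if (length(methods) < 1) stop("at least one method required", call. = FALSE)
  for (m in methods) {
    if (!m$method %in% c("univariate", "plsda"))
      stop("unknown method '", m$method, "'", call. = FALSE)
    if (m$method == "plsda")
      match.arg(m$preprocess, preprocess_methods())
  }
  structure(list(input = input,
                 calibration_fraction = calibration_fraction,
                 stratified = stratified,
                 split_seed = if (is.null(split_seed)) seed else split_seed,
                 methods = methods, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Default method list: univariate + four PLS-DA variants
#' @param n_components Optional fixed latent-variable count for the PLS-DA
#'   entries (`NULL` = leave-one-out CV selection).
#' @return List of method entries for [experiment_config()].
#' @export
default_methods <- function(n_components = NULL) {
  c(list(list(method = "univariate", wavelength = 450)),
    lapply(preprocess_methods(), function(p)
      list(method = "plsda", preprocess = p, n_components = n_components)))
}

method_name <- function(m) {
  if (m$method == "univariate") "univariate"
  else paste0("plsda_", m$preprocess)
}

#' Read an experiment configuration from JSON or YAML
#'
#' Keys mirror [experiment_config()]; `input` is either a string (CSV
#' path) or a nested synthetic-config record, `methods` a list of
#' `{method, preprocess, n_components}` records.
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file.
#' @return An `experiment_config`.
#' @export
experiment_config_from_file <- function(path) {
  cfg <- read_config_file(path)
  input <- cfg$input
  if (is.list(input)) {
    args <- input[intersect(names(input),
                            c("baseline_amplitude", "scatter_multiplicative_sd",
                              "scatter_additive_sd", "noise_sd",
                              "overlap_fraction", "wavelength_start",
                              "wavelength_stop", "wavelength_step", "seed"))]
    if (!is.null(input$profiles))
      args$profiles <- lapply(input$profiles, function(p)
        class_profile(p$label, p$n_samples, p$od_min, p$od_max))
    if (!is.null(input$beer_lambert))
      args$beer_lambert <- do.call(beer_lambert_params, input$beer_lambert)
    if (is.null(args$seed)) args$seed <- cfg$seed
    input <- do.call(synthetic_config, args)
  }
  experiment_config(
    input = input,
    calibration_fraction = cfg$calibration_fraction %||% 0.7,
    stratified = cfg$stratified %||% TRUE,
    split_seed = cfg$split_seed,
    methods = if (is.null(cfg$methods)) default_methods()
      else lapply(cfg$methods, function(m)
        list(method = m$method, preprocess = m$preprocess,
             n_components = m$n_components, wavelength = m$wavelength %||% 450)),
    seed = cfg$seed, output_dir = cfg$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparison experiment
#'
#' Generates (or loads) the labeled spectra, splits them into calibration
#' and validation domains, trains every configured method on the
#' calibration set, predicts both domains, and assembles
#' confusion-matrix/metric reports plus a manifest that makes the run
#' reproducible. If the configuration names an `output_dir`, all
#' artifacts (spectra CSV, split membership, per-method predictions,
#' report tables, manifest) are written there; an existing non-empty
#' directory is never overwritten — a versioned sibling
#' (`<dir>-2`, `<dir>-3`, ...) is created instead.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List with `dataset`, `split`, `models`, `predictions`,
#'   `results` (per-method confusion + metrics), `report` (the
#'   [render_report()] tables), `manifest`, and `output_dir` (or `NULL`).
#' @export
run_experiment <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- "input"
  result <- tryCatch({
    dataset <- if (inherits(config$input, "synthetic_config")) {
      say("stage=input source=synthetic seed=", config$input$seed)
      generate_dataset(config$input)
    } else {
      say("stage=input source=", config$input)
      read_spectra(config$input)
    }
    if (is.null(dataset$labels))
      stop("experiment requires labeled spectra", call. = FALSE)

    stage <- "split"
    split <- split_calibration_validation(
      dataset, config$calibration_fraction,
      stratified = config$stratified, seed = config$split_seed)
    say("stage=split calibration=", n_samples(split$calibration),
        " validation=", n_samples(split$validation))

    stage <- "fit"
    models <- list(); predictions <- list(); results <- list()
    decisions <- list()
    for (m in config$methods) {
      nm <- method_name(m)
      say("stage=fit method=", nm)
      if (m$method == "univariate") {
        fit <- univariate_train(split$calibration, m$wavelength %||% 450)
        pred_cal <- univariate_predict(fit, split$calibration)
        pred_val <- univariate_predict(fit, split$validation)
        decisions[[nm]] <- list(t_low = fit$t_low, t_high = fit$t_high,
                                boundary_tie_rule = "higher severity")
      } else {
        fit <- plsda_train(split$calibration, preprocess = m$preprocess,
                           n_components = m$n_components)
        pred_cal <- plsda_predict(fit, split$calibration)
        pred_val <- plsda_predict(fit, split$validation)
        decisions[[nm]] <- list(
          n_components = fit$n_components,
          components_selected_by_cv = fit$components_selected_by_cv,
          center_y = fit$center_y)
      }
      res <- list(
        calibration = evaluate_predictions(split$calibration$labels, pred_cal),
        validation = evaluate_predictions(split$validation$labels, pred_val))
      for (d in names(res))
        if (length(res[[d]]$metrics$flags))
          decisions[[nm]][[paste0(d, "_metric_flags")]] <- res[[d]]$metrics$flags
      models[[nm]] <- fit
      predictions[[nm]] <- list(calibration = pred_cal, validation = pred_val)
      results[[nm]] <- res
    }

    stage <- "report"
    report <- render_report(results)
    manifest <- list(
      package = "odspectra",
      package_version = as.character(utils::packageVersion("odspectra")),
      r_version = R.version.string,
      seed = config$seed, split_seed = config$split_seed,
      calibration_fraction = config$calibration_fraction,
      stratified = config$stratified,
      input = if (inherits(config$input, "synthetic_config"))
        unclass_config(config$input) else list(path = config$input),
      methods = lapply(config$methods, function(m) m[!vapply(m, is.null, TRUE)]),
      decisions = decisions)

    out_dir <- NULL
    if (!is.null(config$output_dir)) {
      stage <- "write"
      out_dir <- versioned_dir(config$output_dir)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_spectra(dataset, file.path(out_dir, "spectra.csv"))
      utils::write.csv(split$membership, file.path(out_dir, "split.csv"),
                       row.names = FALSE)
      for (nm in names(predictions)) {
        df <- rbind(
          data.frame(sample_id = split$calibration$sample_ids,
                     domain = "calibration",
                     actual = as.character(split$calibration$labels),
                     predicted = as.character(predictions[[nm]]$calibration)),
          data.frame(sample_id = split$validation$sample_ids,
                     domain = "validation",
                     actual = as.character(split$validation$labels),
                     predicted = as.character(predictions[[nm]]$validation)))
        utils::write.csv(df, file.path(out_dir, paste0("predictions_", nm, ".csv")),
                         row.names = FALSE)
      }
      render_report(results, dir = out_dir)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(dataset = dataset, split = split, models = models,
         predictions = predictions, results = results, report = report,
         manifest = manifest, output_dir = out_dir)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$wavelengths <- NULL
  out$profiles <- lapply(out$profiles, unclass)
  out$beer_lambert <- unclass(out$beer_lambert)
  out
}

versioned_dir <- function(dir) {
  if (!dir.exists(dir) || length(list.files(dir, all.files = TRUE,
                                            no.. = TRUE)) == 0)
    return(dir)
  k <- 2
  while (dir.exists(paste0(dir, "-", k))) k <- k + 1
  paste0(dir, "-", k)
}
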