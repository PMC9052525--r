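#!/usr/bin/env Rscript
# Thin command-line wrapper over odspectra::run_experiment().
#
# Usage:
#   Rscript scripts/run_experiment.R --config <file.(json|yaml)>
#       [--output <dir>] [--seed <int>] [--verbose]
#
# The config schema mirrors experiment_config(); see the package vignette.

suppressMessages(library(odspectra))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
config_path <- get_arg("--config")
if (is.null(config_path))
  stop("usage: Rscript scripts/run_experiment.R --config <file> [--output <dir>] [--seed <int>] [--verbose]")

cfg <- experiment_config_from_file(config_path)
out <- get_arg("--output")
if (!is.null(out)) cfg$output_dir <- out
seed <- get_arg("--seed")
if (!is.null(seed)) {
  cfg$seed <- as.integer(seed)
  cfg$split_seed <- as.integer(seed)
  if (inherits(cfg$input, "synthetic_config")) cfg$input$seed <- as.integer(seed)
}

run <- run_experiment(cfg, quiet = !("--verbose" %in% args))
print(run$report$metrics, row.names = FALSE)
if (!is.null(run$output_dir)) cat("artifacts written to", run$output_dir, "\n")
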