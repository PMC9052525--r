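#' Beer-Lambert band parameters
#'
#' Parameters of the forward absorbance model A = epsilon(lambda) * b * c:
#' a Gaussian absorptivity band of height `epsilon_max` centered at
#' `peak_center` (the 450 nm TMB product peak by default), optical path
#' `path_b`, so that the peak absorbance of a sample with concentration `c`
#' is `epsilon_max * path_b * c`.
#'
#' @param epsilon_max Molar absorptivity at the band peak (AU per
#'   concentration unit; the concentration unit is arbitrary but fixed).
#' @param path_b Optical path length (dimensionless scale factor).
#' @param peak_center Band center, nm, in [300, 550].
#' @param peak_width Gaussian standard deviation of the band, nm.
#' @return A `beer_lambert_params` list.
#' @export
beer_lambert_params <- function(epsilon_max = 1, path_b = 1,
                                peak_center = 450, peak_width = 40) {
  stopifnot(epsilon_max > 0, path_b > 0,
            peak_center >= 300, peak_center <= 550, peak_width > 0)
  structure(list(epsilon_max = epsilon_max, path_b = path_b,
                 peak_center = peak_center, peak_width = peak_width),
            class = "beer_lambert_params")
}

#' Per-class OD(450) profile
#'
#' The optical-density band a severity class occupies at the peak
#' wavelength, used to invert the Beer-Lambert model when drawing
#' concentrations.
#'
#' @param label Class label, one of [class_levels()].
#' @param n_samples Number of samples to generate for the class.
#' @param od_min,od_max Noiseless peak-OD support bounds (AU),
#'   `0 <= od_min < od_max`.
#' @return A `class_profile` list.
#' @export
class_profile <- function(label, n_samples, od_min, od_max) {
  label <- as.character(label)
  stopifnot(label %in% class_levels(), n_samples >= 0,
            od_min >= 0, od_min < od_max)
  structure(list(label = label, n_samples = as.integer(n_samples),
                 od_min = od_min, od_max = od_max),
            class = "class_profile")
}

#' Default class OD profiles
#'
#' The three severity classes with the OD(450) bands observed in the
#' motivating DSPP assay data: normal below 0.35, mild 0.35-0.88, severe up
#' to 1.99. Two presets for group sizes are provided: `"study"` uses the
#' clinical group sizes 14/5/11; `"balanced"` uses 10/10/10 (the sizes the
#' study's univariate confusion matrix totals imply).
#'
#' @param preset `"study"` (14/5/11) or `"balanced"` (10/10/10).
#' @return List of three [class_profile()]s in class order.
#' @export
default_profiles <- function(preset = c("study", "balanced")) {
  preset <- match.arg(preset)
  n <- switch(preset, study = c(14L, 5L, 11L), balanced = c(10L, 10L, 10L))
  list(class_profile("normal", n[1], 0.02, 0.35),
       class_profile("mild",   n[2], 0.35, 0.88),
       class_profile("severe", n[3], 0.88, 1.99))
}

#' Synthetic-dataset configuration
#'
#' Everything needed to generate a labeled spectral dataset: per-class OD
#' profiles, the Beer-Lambert band, artifact magnitudes (smooth baseline,
#' per-spectrum multiplicative/additive scatter, i.i.d. channel noise),
#' between-class overlap, the wavelength grid, and a mandatory seed.
#'
#' Artifact defaults are chosen to be small relative to the 0.02-1.99 AU
#' signal range but large enough that per-spectrum normalisation (SNV) and
#' per-wavelength centering/scaling behave differently, as they do on real
#' plate-reader scans.
#'
#' @param profiles List of three [class_profile()]s (one per class, class
#'   order).
#' @param beer_lambert [beer_lambert_params()].
#' @param baseline_amplitude Amplitude (AU) of a fixed smooth baseline that
#'   decays toward long wavelengths.
#' @param scatter_multiplicative_sd SD of the per-spectrum multiplicative
#'   scatter factor (dimensionless).
#' @param scatter_additive_sd SD of the per-spectrum additive offset (AU).
#' @param noise_sd SD of i.i.d. per-wavelength noise (AU).
#' @param overlap_fraction In [0, 0.5): fraction of each class's OD band
#'   width by which its support is stretched past both profile bounds,
#'   creating adjacent-class overlap like that seen in real assay data.
#' @param wavelength_start,wavelength_stop,wavelength_step Grid, nm
#'   (defaults 300, 550, 1: 251 points).
#' @param seed Integer seed; mandatory, the dataset is a pure function of
#'   the configuration.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(profiles = default_profiles(),
                             beer_lambert = beer_lambert_params(),
                             baseline_amplitude = 0.04,
                             scatter_multiplicative_sd = 0.02,
                             scatter_additive_sd = 0.01,
                             noise_sd = 0.005,
                             overlap_fraction = 0.05,
                             wavelength_start = 300,
                             wavelength_stop = 550,
                             wavelength_step = 1,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(profiles) == 3,
            all(vapply(profiles, inherits, logical(1), "class_profile")),
            inherits(beer_lambert, "beer_lambert_params"),
            baseline_amplitude >= 0, scatter_multiplicative_sd >= 0,
            scatter_additive_sd >= 0, noise_sd >= 0,
            overlap_fraction >= 0, overlap_fraction < 0.5,
            wavelength_step > 0, wavelength_stop > wavelength_start)
  grid <- seq(wavelength_start, wavelength_stop, by = wavelength_step)
  if (length(grid) < 2) stop("wavelength grid must have at least 2 points", call. = FALSE)
  labs <- vapply(profiles, `[[`, character(1), "label")
  if (!identical(labs, class_levels()))
    stop("profiles must be one per class in class order", call. = FALSE)
  structure(list(profiles = profiles, beer_lambert = beer_lambert,
                 baseline_amplitude = baseline_amplitude,
                 scatter_multiplicative_sd = scatter_multiplicative_sd,
                 scatter_additive_sd = scatter_additive_sd,
                 noise_sd = noise_sd, overlap_fraction = overlap_fraction,
                 wavelength_start = wavelength_start,
                 wavelength_stop = wavelength_stop,
                 wavelength_step = wavelength_step,
                 wavelengths = grid, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic configuration from JSON or YAML
#'
#' File keys mirror the arguments of [synthetic_config()]; `profiles` is a
#' list of `{label, n_samples, od_min, od_max}` records and `beer_lambert`
#' a record of its four parameters. Missing keys take the defaults; `seed`
#' must be present.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `synthetic_config`.
#' @export
synthetic_config_from_file <- function(path) {
  cfg <- read_config_file(path)
  args <- cfg[intersect(names(cfg),
                        c("baseline_amplitude", "scatter_multiplicative_sd",
                          "scatter_additive_sd", "noise_sd", "overlap_fraction",
                          "wavelength_start", "wavelength_stop",
                          "wavelength_step", "seed"))]
  if (!is.null(cfg$profiles))
    args$profiles <- lapply(cfg$profiles, function(p)
      class_profile(p$label, p$n_samples, p$od_min, p$od_max))
  if (!is.null(cfg$beer_lambert))
    args$beer_lambert <- do.call(beer_lambert_params, cfg$beer_lambert)
  do.call(synthetic_config, args)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format '", ext, "' (use json or yaml)",
            call. = FALSE)
}

# Evaluate expr with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so dataset generation never perturbs user code.
run_seeded <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Draw analyte concentrations for one class
#'
#' Inverts the Beer-Lambert relation at the band peak: concentrations are
#' drawn uniformly so the noiseless peak OD `epsilon_max * path_b * c` lies
#' in the class's OD band, optionally stretched by `overlap_fraction` of
#' the band width past both bounds. With `overlap_fraction = 0` every
#' noiseless peak OD lies strictly inside `[od_min, od_max]`.
#'
#' Uses the current RNG state; seed beforehand for reproducibility
#' ([generate_dataset()] does this from its config seed).
#'
#' @param profile A [class_profile()].
#' @param params [beer_lambert_params()].
#' @param overlap_fraction In [0, 0.5).
#' @return Numeric vector of `profile$n_samples` concentrations.
#' @export
sample_concentrations <- function(profile, params, overlap_fraction = 0) {
  stopifnot(inherits(profile, "class_profile"),
            inherits(params, "beer_lambert_params"),
            overlap_fraction >= 0, overlap_fraction < 0.5)
  if (profile$n_samples == 0) return(numeric(0))
  band <- profile$od_max - profile$od_min
  lo <- profile$od_min - overlap_fraction * band
  hi <- profile$od_max + overlap_fraction * band
  scale <- params$epsilon_max * params$path_b
  conc <- stats::runif(profile$n_samples, lo, hi) / scale
  if (any(conc < 0))
    stop("negative concentration for class '", profile$label,
         "': lower OD bound ", signif(lo, 4),
         " extends below zero; reduce overlap_fraction", call. = FALSE)
  conc
}

baseline_shape <- function(wavelengths, start) {
  # fixed smooth curve decaying toward long wavelengths (unit amplitude at
  # the grid start, 150 nm decay constant)
  exp(-(wavelengths - start) / 150)
}

#' Simulate one absorbance spectrum
#'
#' Forward model: Gaussian Beer-Lambert band scaled by concentration and a
#' per-spectrum multiplicative scatter factor, plus a fixed smooth baseline,
#' a per-spectrum additive offset, and i.i.d. channel noise:
#' \deqn{A(\lambda) = \epsilon_{max} e^{-(\lambda-c_0)^2/2s^2} b\,c\,(1+m)
#'   + \mathrm{baseline}(\lambda) + a + \eta(\lambda)}
#' with \eqn{m \sim N(0, \sigma_{mult})}, \eqn{a \sim N(0, \sigma_{add})}
#' once per spectrum and \eqn{\eta(\lambda)} i.i.d.
#' \eqn{N(0, \sigma_{noise})}.
#'
#' Uses the current RNG state (draws nothing when all noise SDs are zero).
#'
#' @param concentration Analyte concentration, `>= 0`.
#' @param config A [synthetic_config()].
#' @return Numeric absorbance vector on the config's wavelength grid.
#' @export
simulate_spectrum <- function(concentration, config) {
  stopifnot(inherits(config, "synthetic_config"), concentration >= 0)
  bl <- config$beer_lambert
  w <- config$wavelengths
  band <- bl$epsilon_max *
    exp(-(w - bl$peak_center)^2 / (2 * bl$peak_width^2)) * bl$path_b
  m <- if (config$scatter_multiplicative_sd > 0)
    stats::rnorm(1, 0, config$scatter_multiplicative_sd) else 0
  a <- if (config$scatter_additive_sd > 0)
    stats::rnorm(1, 0, config$scatter_additive_sd) else 0
  eta <- if (config$noise_sd > 0)
    stats::rnorm(length(w), 0, config$noise_sd) else numeric(length(w))
  band * concentration * (1 + m) +
    config$baseline_amplitude * baseline_shape(w, config$wavelength_start) +
    a + eta
}

#' Generate a labeled synthetic dataset
#'
#' Draws per-class concentrations ([sample_concentrations()]) and simulates
#' one spectrum per sample ([simulate_spectrum()]), concatenated in class
#' order with stable ids `<label>_<k>`. The result is bit-reproducible from
#' the configuration (including its seed); the caller's RNG state is left
#' untouched.
#'
#' @param config A [synthetic_config()].
#' @return A labeled [spectra_set()] with the per-sample concentrations
#'   attached as attribute `"concentrations"`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run_seeded(config$seed, {
    mats <- list(); ids <- character(0); labs <- character(0); concs <- numeric(0)
    for (pr in config$profiles) {
      conc <- sample_concentrations(pr, config$beer_lambert,
                                    config$overlap_fraction)
      if (pr$n_samples > 0) {
        m <- t(vapply(conc, simulate_spectrum, numeric(length(config$wavelengths)),
                      config = config))
        mats[[length(mats) + 1L]] <- m
        ids <- c(ids, sprintf("%s_%02d", pr$label, seq_len(pr$n_samples)))
        labs <- c(labs, rep(pr$label, pr$n_samples))
        concs <- c(concs, conc)
      }
    }
    mat <- if (length(mats)) do.call(rbind, mats)
      else matrix(0, 0, length(config$wavelengths))
    out <- spectra_set(mat, config$wavelengths, ids,
                       if (length(labs)) labs else NULL)
    attr(out, "concentrations") <- concs
    out
  })
}
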