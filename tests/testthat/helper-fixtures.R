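# Small in-code fixtures shared across test files.

# A tiny well-formed spectra_set: n samples on a short grid, linear spectra.
tiny_spectra <- function(n = 4, wavelengths = c(440, 450, 460),
                         labels = rep(class_levels(), length.out = n)) {
  mat <- outer(seq_len(n) / 10, rep(1, length(wavelengths))) +
    matrix(seq_along(wavelengths) / 100, n, length(wavelengths), byrow = TRUE)
  spectra_set(mat, wavelengths, sprintf("s%02d", seq_len(n)), labels)
}

# A noiseless, overlap-free synthetic configuration (pure Beer-Lambert).
clean_config <- function(seed, profiles = default_profiles(), baseline = 0) {
  synthetic_config(profiles = profiles,
                   baseline_amplitude = baseline,
                   scatter_multiplicative_sd = 0,
                   scatter_additive_sd = 0,
                   noise_sd = 0, overlap_fraction = 0, seed = seed)
}

# Brute-force three-way comparison oracle for OD classification.
brute_force_classify <- function(od, t_low, t_high) {
  rank <- (od >= t_low) + (od >= t_high)
  class_levels()[rank + 1]
}

# Brute-force one-vs-rest counts by per-sample enumeration.
brute_force_truth_table <- function(actual, predicted) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  do.call(rbind, lapply(class_levels(), function(k) {
    data.frame(class = k,
               TP = sum(actual == k & predicted == k),
               FP = sum(actual != k & predicted == k),
               TN = sum(actual != k & predicted != k),
               FN = sum(actual == k & predicted != k))
  }))
}

# Two-class (normal/severe) rank-one predictor matrix: a single latent
# direction separates the classes exactly.
rank_one_two_class <- function(n_per_class = 5, p = 12, seed = 1) {
  set.seed(seed)
  t_vec <- rep(c(-1, 1), each = n_per_class) + rnorm(2 * n_per_class, 0, 0.05)
  p_vec <- rnorm(p)
  list(X = tcrossprod(t_vec, p_vec) + matrix(rnorm(2 * n_per_class * p, 0, 1e-4),
                                             2 * n_per_class, p),
       labels = rep(c("normal", "severe"), each = n_per_class))
}
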