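test_that("class encoding is one-hot in fixed column order", {
  Y <- encode_classes(c("normal", "severe"))
  expect_equal(unname(Y), rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(colnames(Y), class_levels())
  expect_equal(dim(encode_classes(character(0))), c(0L, 3L))
  set.seed(1)
  Yr <- encode_classes(sample(class_levels(), 25, replace = TRUE))
  expect_equal(unname(rowSums(Yr)), rep(1, 25))
  expect_error(encode_classes(c("normal", "bad")), "unknown class label")
})

test_that("full-component NIPALS reproduces the least-squares oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 9; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    Y <- encode_classes(sample(class_levels(), n, replace = TRUE))
    fit <- fit_plsda(X, Y, n_components = p)
    B_ols <- solve(crossprod(X), crossprod(X, Y))
    expect_equal(predict_responses(fit, X), X %*% B_ols, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # and with centered X / Y against an intercept-included OLS oracle
    Xc <- scale(X, scale = FALSE)
    fitc <- fit_plsda(Xc, Y, n_components = p, center_y = TRUE)
    ols <- stats::lm.fit(cbind(1, X), Y)
    expect_equal(predict_responses(fitc, Xc),
                 cbind(1, X) %*% ols$coefficients, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("successive score vectors are mutually orthogonal", {
  set.seed(7)
  X <- matrix(rnorm(20 * 15), 20, 15)
  Y <- encode_classes(rep(class_levels(), length.out = 20))
  fit <- fit_plsda(X, Y, n_components = 8, center_y = TRUE)
  G <- crossprod(fit$scores)
  off <- abs(G - diag(diag(G)))
  expect_lt(max(off) / max(diag(G)), 1e-8)
})

test_that("loadings reconstruct X with non-increasing residual norm", {
  set.seed(8)
  X <- scale(matrix(rnorm(15 * 10), 15, 10), scale = FALSE)
  Y <- encode_classes(rep(class_levels(), 5))
  fit <- fit_plsda(X, Y, n_components = 6, center_y = TRUE)
  resid_norm <- vapply(1:6, function(k) {
    Tk <- fit$scores[, 1:k, drop = FALSE]
    Pk <- fit$P[, 1:k, drop = FALSE]
    norm(X - tcrossprod(Tk, Pk), "F")
  }, numeric(1))
  expect_true(all(diff(resid_norm) <= 1e-10))
  expect_lt(resid_norm[6], norm(X, "F"))
})

test_that("one latent variable separates rank-one two-class data", {
  d <- rank_one_two_class()
  Y <- encode_classes(d$labels)
  fit <- fit_plsda(d$X, Y, n_components = 1, center_y = TRUE)
  pred <- assign_class(predict_responses(fit, d$X))
  expect_equal(as.character(pred), d$labels)
})

test_that("response prediction preserves calibration class frequencies under centering", {
  set.seed(9)
  labs <- sample(rep(class_levels(), times = c(6, 3, 5)))
  X <- scale(matrix(rnorm(14 * 20), 14, 20), scale = FALSE)
  Y <- encode_classes(labs)
  fit <- fit_plsda(X, Y, n_components = 4, center_y = TRUE)
  Yhat <- predict_responses(fit, X)
  freq <- c(6, 3, 5) / 14
  expect_equal(unname(colMeans(Yhat)), freq, tolerance = 1e-10)
  # an all-zero preprocessed row predicts exactly the class frequencies
  expect_equal(unname(drop(predict_responses(fit, matrix(0, 1, 20)))), freq,
               tolerance = 1e-10)
  expect_error(predict_responses(fit, matrix(0, 1, 7)), "grid mismatch")
})

test_that("arg-max assignment breaks exact ties toward lower severity", {
  expect_equal(as.character(assign_class(c(0.9, 0.3, -0.2))), "normal")
  expect_equal(as.character(assign_class(c(0.5, 0.5, 0.1))), "normal")
  expect_equal(as.character(assign_class(c(0.1, 0.4, 0.4))), "mild")
  expect_equal(as.character(assign_class(c(-0.1, 0.2, 0.7))), "severe")
  expect_equal(as.character(assign_class(rbind(c(1, 0, 0), c(0, 0, 1)))),
               c("normal", "severe"))
  expect_error(assign_class(c(1, NA, 0)), "non-finite")
})

test_that("component-count selection finds the separating dimension and ignores order", {
  d <- rank_one_two_class(n_per_class = 6)
  Y <- encode_classes(d$labels)
  expect_equal(select_n_components(d$X, Y, max_components = 4, center_y = TRUE), 1L)
  expect_equal(select_n_components(d$X, Y, max_components = 1), 1L)
  set.seed(10)
  perm <- sample(nrow(d$X))
  expect_equal(
    select_n_components(d$X[perm, ], Y[perm, ], max_components = 4, center_y = TRUE),
    select_n_components(d$X, Y, max_components = 4, center_y = TRUE))
})

test_that("fit is deterministic and bounds are enforced", {
  set.seed(11)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- encode_classes(rep(class_levels(), 4))
  expect_identical(fit_plsda(X, Y, 3), fit_plsda(X, Y, 3))
  expect_error(fit_plsda(X, Y, 0), "n_components")
  expect_error(fit_plsda(X, Y, 12), "n_components")
  expect_error(fit_plsda(X[1:2, ], Y[1:2, ], 1), "at least 3 samples")
})

test_that("first NIPALS scores agree with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  ds <- generate_dataset(synthetic_config(seed = 12))
  Xc <- scale(ds$absorbance, scale = FALSE)
  Yc <- scale(encode_classes(ds$labels), scale = FALSE)
  mine <- fit_plsda(Xc, encode_classes(ds$labels), n_components = 3,
                    center_y = TRUE)
  ref <- mixOmics::pls(Xc, Yc, ncomp = 3, scale = FALSE, mode = "regression")
  for (k in 1:3)
    expect_gt(abs(cor(mine$scores[, k], ref$variates$X[, k])), 1 - 1e-8)
})

test_that("the trained classifier pipeline is exact on clean separable spectra", {
  ds <- generate_dataset(clean_config(seed = 13))
  # add tiny channel noise so spectra are full rank for every preprocessing
  cfg <- synthetic_config(noise_sd = 0.002, overlap_fraction = 0,
                          scatter_multiplicative_sd = 0,
                          scatter_additive_sd = 0, seed = 13)
  ds <- generate_dataset(cfg)
  for (p in preprocess_methods()) {
    fit <- plsda_train(ds, preprocess = p, n_components = 10)
    expect_equal(unname(plsda_predict(fit, ds)), ds$labels, label = p)
  }
})
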