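#' Dummy-code class labels
#'
#' One-hot (indicator) coding of the three severity classes, columns in
#' class order (normal, mild, severe). This is the response matrix Y that
#' PLS-DA regresses on the spectra.
#'
#' @param labels Class labels (see [class_levels()]).
#' @return Numeric matrix, samples x 3, each row one 1 and two 0s.
#' @export
encode_classes <- function(labels) {
  labels <- as_class_label(labels)
  if (anyNA(labels)) stop("missing class label(s)", call. = FALSE)
  lv <- class_levels()
  Y <- matrix(0, length(labels), length(lv), dimnames = list(NULL, lv))
  if (length(labels)) Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Fit a PLS2 regression by NIPALS
#'
#' Component-wise nonlinear iterative partial least squares on an
#' (already preprocessed) predictor matrix `X` and a dummy response matrix
#' `Y`. Per component: `u` is initialised to the `Y` column of largest
#' variance (deterministic); the iteration
#' `w = X'u / ||X'u||`, `t = Xw`, `q = Y't / t't`, `u = Yq / q'q`
#' runs until the score vector `t` changes by less than `tol` (relative);
#' `X` is then deflated by `t p'` with `p = X't / t't` and `Y` by `t q'`.
#' Regression coefficients are accumulated as `B = W (P'W)^{-1} Q'`.
#'
#' When `center_y = TRUE` the response is centered with its own column
#' means, which are stored and re-added at prediction time (used together
#' with column-wise X preprocessing, the standard PLS2 practice).
#'
#' @param X Numeric matrix, samples x wavelengths, preprocessing already
#'   applied.
#' @param Y Dummy response matrix from [encode_classes()] (raw, uncentered).
#' @param n_components Number of latent variables,
#'   `1 <= A <= min(n - 1, p)`.
#' @param center_y Center `Y` with calibration means (default `FALSE`).
#' @param tol Relative convergence tolerance on the score vector (1e-10).
#' @param max_iter Maximum NIPALS iterations per component (5000; the
#'   inner iteration is a power method whose convergence slows as the two
#'   leading eigenvalues of the deflated cross-covariance approach each
#'   other, which noise-dominated late components routinely do).
#' @return A `plsda_model` with weights `W` (p x A), loadings `P` (p x A),
#'   `Q` (3 x A), scores `T` (n x A), coefficients `B` (p x 3), `y_means`,
#'   `n_components`, `class_order`.
#' @export
fit_plsda <- function(X, Y, n_components, center_y = FALSE,
                      tol = 1e-10, max_iter = 5000L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, p))
    stop("n_components must be in [1, ", min(n - 1, p), "], got ", A,
         call. = FALSE)
  y_means <- if (center_y) colMeans(Y) else rep(0, ncol(Y))
  Xw <- X; Yw <- sweep(Y, 2, y_means)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, ncol(Y), A); Tsc <- matrix(0, n, A)
  for (a in seq_len(A)) {
    u <- Yw[, which.max(apply(Yw, 2, stats::var))]
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xw, u))
      wn <- sqrt(sum(w^2))
      if (wn == 0)
        stop("X deflated to zero at component ", a,
             "; reduce n_components", call. = FALSE)
      w <- w / wn
      tt <- drop(Xw %*% w)
      q <- drop(crossprod(Yw, tt)) / sum(tt^2)
      u <- drop(Yw %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1e-300)) {
        converged <- TRUE; break
      }
      t_old <- tt
    }
    if (!converged)
      stop("NIPALS did not converge at component ", a, " after ",
           max_iter, " iterations", call. = FALSE)
    pa <- drop(crossprod(Xw, tt)) / sum(tt^2)
    Xw <- Xw - tcrossprod(tt, pa)
    Yw <- Yw - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pa; Q[, a] <- q; Tsc[, a] <- tt
  }
  B <- coefficients_from_factors(W, P, Q, A)
  structure(list(W = W, P = P, Q = Q, scores = Tsc, B = B,
                 y_means = y_means, n_components = A,
                 class_order = class_levels()),
            class = "plsda_model")
}

coefficients_from_factors <- function(W, P, Q, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  Qk <- Q[, seq_len(k), drop = FALSE]
  M <- crossprod(Pk, Wk)
  inv <- tryCatch(solve(M), error = function(e)
    stop("singular (P'W) at ", k, " components: ", conditionMessage(e),
         call. = FALSE))
  Wk %*% inv %*% t(Qk)
}

#' Predict continuous class responses
#'
#' `Yhat = X_new B (+ calibration Y means when the model centered Y)`.
#' `X_new` must be on the training grid with the same preprocessing already
#' applied. A truncated model (fewer components than fitted) can be
#' requested with `n_components`.
#'
#' @param model A `plsda_model`.
#' @param X_new Numeric matrix, samples x wavelengths.
#' @param n_components Number of components to use (default: all fitted).
#' @return Numeric matrix, samples x 3 continuous responses.
#' @export
predict_responses <- function(model, X_new, n_components = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(model$B))
    stop("wavelength grid mismatch: model has ", nrow(model$B),
         " variables, new data has ", ncol(X_new), call. = FALSE)
  B <- if (is.null(n_components) || n_components == model$n_components)
    model$B
  else coefficients_from_factors(model$W, model$P, model$Q, n_components)
  sweep(X_new %*% B, 2, model$y_means, "+")
}

#' Assign a discrete class from continuous responses
#'
#' Arg-max rule over the three dummy responses; an exact tie goes to the
#' lower-severity class (the conservative direction for a continuous
#' response tie, and the deterministic one).
#'
#' @param responses Numeric vector of 3 responses, or a samples x 3 matrix.
#' @return Factor of class labels.
#' @export
assign_class <- function(responses) {
  if (!is.matrix(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != 3) stop("expected 3 response columns", call. = FALSE)
  if (!all(is.finite(responses))) stop("non-finite response(s)", call. = FALSE)
  idx <- apply(responses, 1, which.max)  # which.max ties -> first = lower severity
  as_class_label(class_levels()[idx])
}

#' Choose the number of latent variables by leave-one-out CV
#'
#' Fits the model n times leaving one sample out, classifies the held-out
#' sample with 1..`max_components` latent variables, and returns the
#' smallest component count achieving the minimum total misclassification
#' count. Invariant to sample order.
#'
#' @param X Preprocessed predictor matrix.
#' @param Y Dummy response matrix.
#' @param max_components Upper bound on components (capped at
#'   `min(n - 2, p)` so every fold can fit it).
#' @param center_y Passed to [fit_plsda()]; each fold centers Y with its
#'   own means.
#' @return Integer component count.
#' @export
select_n_components <- function(X, Y, max_components = 10, center_y = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  kmax <- min(as.integer(max_components), n - 2L, ncol(X))
  if (kmax < 1) stop("too few samples to cross-validate", call. = FALSE)
  errors <- integer(kmax)
  actual <- assign_class(Y)
  for (i in seq_len(n)) {
    fit <- fit_plsda(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                     n_components = kmax, center_y = center_y)
    for (k in seq_len(kmax)) {
      pred <- assign_class(predict_responses(fit, X[i, , drop = FALSE],
                                             n_components = k))
      errors[k] <- errors[k] + (pred != actual[i])
    }
  }
  which.min(errors)  # smallest count achieving the minimum
}

#' Train a PLS-DA classifier on a calibration set
#'
#' End-to-end training: fits the preprocessing model on the calibration
#' set, applies it, dummy-codes the labels, optionally selects the number
#' of latent variables by leave-one-out cross-validation, and fits the
#' NIPALS model. The dummy response is centered with calibration means
#' under `mean_center` and `autoscale` preprocessing (column-wise X
#' treatments) and left raw under `none` and `snv`; override with
#' `center_y`.
#'
#' @param calibration Labeled [spectra_set()].
#' @param preprocess One of [preprocess_methods()].
#' @param n_components Latent-variable count; `NULL` (default) selects by
#'   leave-one-out CV capped at `max_components`.
#' @param max_components CV cap (default 10).
#' @param center_y Override the Y-centering rule (logical).
#' @return A `plsda_classifier` wrapping the `plsda_model`, the fitted
#'   `preprocess_model`, and the training grid.
#' @export
plsda_train <- function(calibration, preprocess = "none",
                        n_components = NULL, max_components = 10,
                        center_y = NULL) {
  preprocess <- match.arg(preprocess, preprocess_methods())
  if (is.null(calibration$labels))
    stop("calibration set is unlabeled", call. = FALSE)
  if (is.null(center_y))
    center_y <- preprocess %in% c("mean_center", "autoscale")
  pm <- fit_preprocess(preprocess, calibration)
  Xc <- apply_preprocess(pm, calibration)$absorbance
  Y <- encode_classes(calibration$labels)
  selected <- FALSE
  if (is.null(n_components)) {
    n_components <- select_n_components(Xc, Y, max_components = max_components,
                                        center_y = center_y)
    selected <- TRUE
  }
  model <- fit_plsda(Xc, Y, n_components = n_components, center_y = center_y)
  structure(list(model = model, preprocess_model = pm,
                 preprocess = preprocess, center_y = center_y,
                 n_components = model$n_components,
                 components_selected_by_cv = selected,
                 training_grid = calibration$wavelengths),
            class = "plsda_classifier")
}

#' @export
print.plsda_classifier <- function(x, ...) {
  cat("<plsda_classifier> preprocess=", x$preprocess,
      " components=", x$n_components,
      if (x$components_selected_by_cv) " (LOO-CV)" else "",
      " center_y=", x$center_y, "\n", sep = "")
  invisible(x)
}

#' Predict classes with a trained PLS-DA classifier
#'
#' Applies the stored preprocessing model, computes continuous responses,
#' and assigns classes by the arg-max rule.
#'
#' @param classifier A `plsda_classifier` from [plsda_train()].
#' @param dataset A [spectra_set()] on the training grid.
#' @return Factor of predicted labels, named by sample id.
#' @export
plsda_predict <- function(classifier, dataset) {
  stopifnot(inherits(classifier, "plsda_classifier"))
  Xp <- apply_preprocess(classifier$preprocess_model, dataset)$absorbance
  resp <- predict_responses(classifier$model, Xp)
  stats::setNames(assign_class(resp), dataset$sample_ids)
}
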