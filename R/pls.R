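#' Fit a univariate NIPALS partial least squares regression
#'
#' Classic NIPALS PLSR for a single response: components are extracted by
#' alternating weight/score/loading updates with deflation, projecting the
#' predictors onto latent directions of maximal covariance with the response.
#' Predictors are column-centered internally but not variance-scaled
#' (reflectance shares units across bands); the response is expected already
#' z-scored (see [standardize_fit_apply()]) and is centered defensively.
#'
#' @param X `n x b` predictor matrix (spectra).
#' @param y Response vector, length `n`.
#' @param n_components Number of latent components A,
#'   `1 <= A <= min(n - 1, b)`.
#' @param band_indices Optional indices of `X`'s columns within a fuller
#'   grid, carried for bookkeeping during band selection.
#' @return Object of class `pls_model` with fields `n_components`, `x_mean`,
#'   `y_center`, `weights` (b x A, unit-norm columns), `x_loadings` (b x A),
#'   `y_loadings` (A), `coefficients` (per-band regression coefficients,
#'   `B = W (P'W)^{-1} q`), `band_indices`.
#' @export
fit_pls <- function(X, y, n_components, band_indices = seq_len(ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X); b <- ncol(X)
  if (n < 2) stop2("fit_pls: need at least 2 samples")
  if (length(y) != n) stop2("fit_pls: length(y) must equal nrow(X)")
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, b))
    stop2("fit_pls: n_components must lie in 1..min(n-1, bands)")
  if (sd(y) == 0) stop2("fit_pls: zero-variance response")
  x_mean <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_center
  x0 <- sum(Xc^2) + 1e-300
  W <- matrix(0, b, A); P <- matrix(0, b, A); q <- numeric(A)
  got <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn == 0) break
    w <- w / wn
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= 1e-12 * x0) break
    p <- drop(crossprod(Xc, t_)) / tt
    qa <- sum(yc * t_) / tt
    W[, a] <- w; P[, a] <- p; q[a] <- qa
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - qa * t_
    got <- a
  }
  if (got == 0L) stop2("fit_pls: rank-deficient predictors, no component extracted")
  W <- W[, seq_len(got), drop = FALSE]
  P <- P[, seq_len(got), drop = FALSE]
  q <- q[seq_len(got)]
  B <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_components = got, x_mean = x_mean, y_center = y_center,
                 weights = W, x_loadings = P, y_loadings = q,
                 coefficients = B, band_indices = band_indices),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s), %d bands\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param model A [fit_pls()] model.
#' @param X_new `m x b` matrix with the model's band count.
#' @return Numeric vector of predictions in the units of the fitted response.
#' @export
predict_pls <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- if (is.null(dim(X_new))) matrix(X_new, 1) else as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean))
    stop2("predict_pls: band count mismatch")
  drop(sweep(X_new, 2, model$x_mean) %*% model$coefficients) + model$y_center
}

#' Leave-one-out PRESS at a fixed component count
#'
#' The predicted residual error sum of squares
#' `sum_i (y_i - yhat_{-i})^2`, where each `yhat_{-i}` comes from an honest
#' refit on the remaining `n - 1` samples (no shortcut formulas). The
#' component count is capped at `min(n - 2, bands)` so every fold is
#' estimable.
#'
#' @param X `n x b` predictor matrix, `n >= 3`.
#' @param y Response vector.
#' @param n_components Component count to evaluate.
#' @return PRESS scalar (squared response units).
#' @export
loo_press <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop2("loo_press: need at least 3 samples")
  a <- min(as.integer(n_components), nrow(X) - 2L, ncol(X))
  if (a < 1) stop2("loo_press: no estimable component count")
  profile <- drop(cpp_press_profile(X, as.numeric(y), a))
  profile[a]
}

#' Select the PLS component count by leave-one-out PRESS
#'
#' Computes the LOO PRESS for every candidate component count `1..a_max` and
#' returns the smallest count attaining the minimum (ties broken toward
#' parsimony).
#'
#' @param X `n x b` predictor matrix.
#' @param y Response vector.
#' @param a_max Largest candidate component count; capped at
#'   `min(n - 2, bands)`. Default 15, which covers common chemometric
#'   practice while keeping the cross-validation tractable.
#' @return Object of class `press_profile`: `press` (vector over candidate
#'   counts) and `a_star` (selected count).
#' @export
select_components <- function(X, y, a_max = 15) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop2("select_components: need at least 3 samples")
  a_eff <- min(as.integer(a_max), nrow(X) - 2L, ncol(X))
  if (a_eff < 1) stop2("select_components: no estimable component count")
  press <- drop(cpp_press_profile(X, as.numeric(y), a_eff))
  structure(list(press = press, a_star = which.min(press)),
            class = "press_profile")
}

#' @export
print.press_profile <- function(x, ...) {
  cat("LOO PRESS profile over", length(x$press), "component counts;",
      "selected A =", x$a_star, "\n")
  invisible(x)
}
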