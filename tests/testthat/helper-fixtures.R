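## Shared fixtures, all generated in code under fixed seeds.

## A small synthetic study for unit tests: 40 samples, 40 bands.
small_table <- function(n1 = 20, n2 = 20, n_bands = 40, seed = 7,
                        optics = optics_config()) {
  generate_study(study_config(n1, n2, n_bands, seed = seed), optics = optics)
}

## Full-size study on the reduced 60-band grid used for recovery checks.
study_table_60 <- function(seed = 1, optics = optics_config()) {
  generate_study(study_config(n_bands = 60, seed = seed), optics = optics)
}

## Random dense regression fixture: y linear in X plus noise.
rand_fixture <- function(n, b, seed, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * b), n, b)
  beta <- rnorm(b)
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, noise))
}

## Brute-force leave-one-out PRESS: n independent fit/predict calls through
## the public interface. This is the oracle the fast kernel must match.
brute_force_loo <- function(X, y, n_components) {
  n <- nrow(X)
  a <- min(n_components, n - 2, ncol(X))
  sum(vapply(seq_len(n), function(i) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], a)
    (y[i] - predict_pls(fit, X[i, , drop = FALSE]))^2
  }, numeric(1)))
}

## Three-point column with prescribed sample mean and SD.
column_with_moments <- function(m, s) m + s * c(-1, 0, 1)
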