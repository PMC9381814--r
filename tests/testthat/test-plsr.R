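test_that("full-component PLS reaches the exact-fit limit on noiseless data", {
  fx <- rand_fixture(20, 4, seed = 1, noise = 0)
  fit <- fit_pls(fx$X, fx$y, 4)
  expect_equal(predict_pls(fit, fx$X), fx$y, tolerance = 1e-8)
})

test_that("the first weight vector is the normalized cross-covariance", {
  fx <- rand_fixture(30, 6, seed = 2)
  fit <- fit_pls(fx$X, fx$y, 1)
  Xc <- scale(fx$X, scale = FALSE)
  yc <- fx$y - mean(fx$y)
  w_ref <- drop(crossprod(Xc, yc))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(drop(fit$weights), w_ref, tolerance = 1e-12)
  expect_equal(sqrt(colSums(fit$weights^2)), 1)  # unit-norm weights
})

test_that("fitting is invariant to sample order", {
  fx <- rand_fixture(25, 5, seed = 3)
  set.seed(4)
  perm <- sample(25)
  f1 <- fit_pls(fx$X, fx$y, 3)
  f2 <- fit_pls(fx$X[perm, ], fx$y[perm], 3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("prediction is centered, consistent and linear in the coefficients", {
  fx <- rand_fixture(20, 5, seed = 5)
  z <- standardize_fit_apply(fx$y)$z
  fit <- fit_pls(fx$X, z, 3)
  # a row equal to the training mean predicts the response center (0)
  expect_equal(predict_pls(fit, matrix(fit$x_mean, 1)), 0, tolerance = 1e-10)
  # stored coefficients reproduce the NIPALS state: B = W (P'W)^{-1} q
  B_ref <- drop(fit$weights %*%
                  solve(crossprod(fit$x_loadings, fit$weights),
                        fit$y_loadings))
  expect_equal(fit$coefficients, B_ref, tolerance = 1e-10)
  # hand-doubling the coefficients doubles centered predictions
  doubled <- fit
  doubled$coefficients <- 2 * fit$coefficients
  p1 <- predict_pls(fit, fx$X) - fit$y_center
  p2 <- predict_pls(doubled, fx$X) - fit$y_center
  expect_equal(p2, 2 * p1, tolerance = 1e-10)
  expect_error(predict_pls(fit, matrix(0, 2, 4)), "band count")
})

test_that("rank and degeneracy guards fire", {
  fx <- rand_fixture(10, 5, seed = 6)
  expect_error(fit_pls(fx$X, fx$y, 10), "n_components")
  expect_error(fit_pls(fx$X, rep(1, 10), 2), "zero-variance")
})

test_that("full-rank PLS equals least squares and training RSS is monotone", {
  fx <- rand_fixture(40, 5, seed = 7, noise = 0.5)
  fit <- fit_pls(fx$X, fx$y, 5)
  ols <- lm(fx$y ~ fx$X)
  expect_equal(predict_pls(fit, fx$X), unname(fitted(ols)), tolerance = 1e-6)
  rss <- vapply(1:5, function(a) {
    sum((fx$y - predict_pls(fit_pls(fx$X, fx$y, a), fx$X))^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("leave-one-out PRESS matches the brute-force refit oracle", {
  cases <- list(c(12, 3, 2), c(20, 5, 3), c(30, 10, 6), c(15, 8, 4),
                c(25, 4, 2))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    fx <- rand_fixture(cs[1], cs[2], seed = 100 + k, noise = 0.3)
    expect_equal(loo_press(fx$X, fx$y, cs[3]),
                 brute_force_loo(fx$X, fx$y, cs[3]), tolerance = 1e-10)
  }
})

test_that("PRESS behaves sensibly on noise and duplicated data", {
  # response independent of X: PRESS stays near n (standardized noise)
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5)
  y <- standardize_fit_apply(rnorm(n))$z
  expect_gt(loo_press(X, y, 1), n * 0.5)
  # duplicating an informative dataset lowers PRESS
  fx <- rand_fixture(15, 4, seed = 10, noise = 0.3)
  p1 <- loo_press(fx$X, fx$y, 2)
  p2 <- loo_press(rbind(fx$X, fx$X), c(fx$y, fx$y), 2)
  expect_lt(p2, p1)
})

test_that("PRESS and coefficients are scale-equivariant in y", {
  fx <- rand_fixture(20, 5, seed = 11, noise = 0.2)
  c_ <- 3.7
  f1 <- fit_pls(fx$X, fx$y, 3)
  f2 <- fit_pls(fx$X, c_ * fx$y, 3)
  expect_equal(f2$coefficients, c_ * f1$coefficients, tolerance = 1e-10)
  expect_equal(loo_press(fx$X, c_ * fx$y, 3),
               c_^2 * loo_press(fx$X, fx$y, 3), tolerance = 1e-8)
})

test_that("component selection minimizes PRESS with parsimony tie-breaks", {
  # one dominant informative band plus low-variance distractors: a single
  # component suffices and extra components only chase noise
  set.seed(12)
  n <- 40
  X <- cbind(rnorm(n), matrix(rnorm(n * 5, 0, 0.05), n, 5))
  set.seed(99)
  y <- 2 * X[, 1] + rnorm(n, 0, 0.5)
  prof <- select_components(X, y, a_max = 5)
  expect_equal(prof$a_star, 1)
  expect_true(all(diff(prof$press) >= 0))   # monotone past the minimum here
  # forced single candidate
  expect_equal(select_components(X, y, a_max = 1)$a_star, 1)
  # pure-noise response: no component count undercuts the one-component
  # PRESS, and no count drops below the no-fit floor
  set.seed(13)
  y2 <- standardize_fit_apply(rnorm(n))$z
  prof2 <- select_components(X, y2, a_max = 6)
  expect_equal(prof2$a_star, 1)
  expect_true(all(prof2$press >= prof2$press[1]))
  expect_true(all(prof2$press > n * 0.5))
})
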