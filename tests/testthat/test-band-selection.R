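test_that("band CV profile implements SD/Mean x 100 with guards", {
  # a column with sample mean 7.00 and SD 6.60 has CV 94.29%
  x1 <- column_with_moments(7.00, 6.60)
  x2 <- rep(0.25, 3)                      # constant -> CV 0
  x3 <- column_with_moments(1, 0.2)
  X <- cbind(x1, x2, x3)
  prof <- band_cv_profile(X, c(500, 600, 700))
  expect_equal(prof$cv_percent[1], 6.60 / 7.00 * 100, tolerance = 1e-12)
  expect_equal(prof$cv_percent[2], 0)
  # scale invariance
  prof2 <- band_cv_profile(cbind(3 * x1, x2, 3 * x3), c(500, 600, 700))
  expect_equal(prof2$cv_percent[c(1, 3)], prof$cv_percent[c(1, 3)],
               tolerance = 1e-12)
  # zero-mean band flagged non-finite
  prof3 <- band_cv_profile(cbind(x1, c(-1, 0, 1)), c(500, 600))
  expect_true(is.na(prof3$cv_percent[2]))
  expect_error(band_cv_profile(X[1, , drop = FALSE], c(500, 600, 700)),
               "2 samples")
})

test_that("range partition splits at the boundary deterministically", {
  wl <- seq(400, 1000, length.out = 300)
  part <- partition_bands(wl)
  expect_equal(part$low_range, which(wl <= 717.08))
  expect_equal(part$high_range, which(wl > 717.08))
  expect_length(intersect(part$low_range, part$high_range), 0)
  expect_equal(sort(c(part$low_range, part$high_range)), seq_along(wl))
  expect_warning(p1 <- partition_bands(wl, 399), "empty")
  expect_length(p1$low_range, 0)
  expect_warning(p2 <- partition_bands(wl, 1001), "empty")
  expect_length(p2$high_range, 0)
})

test_that("backward elimination keeps informative bands", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  pos <- c(3, 7)                     # the two informative bands
  y <- standardize_fit_apply(X[, 3] - X[, 7] + rnorm(n, 0, 0.05))$z
  trace <- backward_elimination(X, y, a_max = 5)
  expect_true(all(pos %in% trace$surviving_bands))
  # the trace is internally consistent
  expect_equal(length(trace$press_by_step), ncol(X) - 2 + 1)
  expect_lte(trace$press_by_step[trace$best_step + 1], trace$press_by_step[1])
  expect_setequal(trace$surviving_bands,
                  trace$elimination_order[(trace$best_step + 1):ncol(X)])
})

test_that("two-band floor yields a single-entry trace", {
  fx <- rand_fixture(20, 2, seed = 22, noise = 0.1)
  z <- standardize_fit_apply(fx$y)$z
  trace <- backward_elimination(fx$X, z, a_max = 2)
  expect_length(trace$press_by_step, 1)
  expect_equal(trace$best_step, 0L)
  expect_setequal(trace$surviving_bands, 1:2)
})

test_that("voting counts conserve survivors and respect thresholds", {
  tbl <- small_table(n1 = 15, n2 = 15, n_bands = 30, seed = 23)
  part <- partition_bands(wavelengths(tbl))
  ft <- vote_sensitive_bands(tbl, "BABA", part$low_range, R = 3,
                             threshold = 1, seed = 31, a_max = 5)
  # conservation: total votes equal the summed sizes of per-repetition
  # surviving sets, reconstructed from the same child seeds
  X <- spectra_matrix(tbl)[, part$low_range]
  y <- concentration_matrix(tbl)[, "BABA"]
  n <- nrow(X)
  sizes <- vapply(1:3, function(r) {
    set.seed(aminospec:::child_seed(31, aminospec:::SEED_STAGE[["voting"]], r))
    tr <- sample.int(n, round(0.7 * n))
    z <- standardize_fit_apply(y[tr])$z
    length(backward_elimination(X[tr, ], z, a_max = 5,
                                band_indices = part$low_range)$surviving_bands)
  }, numeric(1))
  expect_equal(sum(ft$count), sum(sizes))
  # single repetition, zero threshold: the voted set IS the surviving set
  ft1 <- vote_sensitive_bands(tbl, "BABA", part$low_range, R = 1,
                              threshold = 0, seed = 31, a_max = 5)
  set.seed(aminospec:::child_seed(31, aminospec:::SEED_STAGE[["voting"]], 1))
  tr <- sample.int(n, round(0.7 * n))
  z <- standardize_fit_apply(y[tr])$z
  tr1 <- backward_elimination(X[tr, ], z, a_max = 5,
                              band_indices = part$low_range)
  expect_setequal(sensitive_bands(ft1), tr1$surviving_bands)
  # threshold = R can never be exceeded (strict inequality)
  ftR <- vote_sensitive_bands(tbl, "BABA", part$low_range, R = 2,
                              threshold = 2, seed = 31, a_max = 5)
  expect_length(sensitive_bands(ftR), 0)
  expect_error(vote_sensitive_bands(tbl, "BABA", part$low_range, R = 2,
                                    threshold = 3, seed = 31), "exceed")
})

test_that("raising the vote threshold never enlarges the sensitive set", {
  tbl <- small_table(n1 = 15, n2 = 15, n_bands = 30, seed = 24)
  part <- partition_bands(wavelengths(tbl))
  ft <- vote_sensitive_bands(tbl, "Orn", part$low_range, R = 4,
                             threshold = 0, seed = 1, a_max = 5)
  sets <- lapply(0:4 - 1, function(th) ft$band[ft$count > th])
  for (k in 2:length(sets)) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  # determinism
  ft2 <- vote_sensitive_bands(tbl, "Orn", part$low_range, R = 4,
                              threshold = 0, seed = 1, a_max = 5)
  expect_identical(ft, ft2)
})

test_that("voting recovers the planted signature bands of a strong analyte", {
  tbl <- small_table(n1 = 60, n2 = 60, n_bands = 60, seed = 25)
  wl <- wavelengths(tbl)
  part <- partition_bands(wl)
  R <- 5
  ft <- vote_sensitive_bands(tbl, "BABA", part$low_range, R = R,
                             threshold = R - 1, seed = 2)
  own <- analyte_signature_centers(optics_config(), "BABA")
  for (cn in own) {
    nearest <- which.min(abs(wl - cn))
    expect_gte(ft$count[ft$band == nearest], 0.8 * R)
  }
})
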