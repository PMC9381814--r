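test_that("evaluation metrics match hand arithmetic and their identities", {
  y <- c(1, 2, 3)
  m <- compute_metrics(y, c(2, 2, 2))       # the test-mean predictor
  expect_equal(m$r2, 0)                     # mean predictor has R2 exactly 0
  expect_equal(m$rmse, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(m$re, sqrt(2 / 3) / 2 * 100, tolerance = 1e-12)
  expect_equal(m$rpd, 1 / sqrt(2 / 3), tolerance = 1e-12)
  # perfect prediction
  p <- compute_metrics(y, y)
  expect_equal(p$r2, 1)
  expect_equal(p$rmse, 0)
  expect_equal(p$re, 0)
  expect_identical(p$rpd, Inf)
  # identities on random metric sets
  set.seed(31)
  for (k in 1:20) {
    yt <- rlnorm(15, 2, 0.8)
    yp <- yt + rnorm(15, 0, 0.5)
    ms <- compute_metrics(yt, yp)
    expect_equal(ms$re, ms$rmse / ms$ybar * 100, tolerance = 1e-10)
    expect_equal(ms$rpd, ms$sd / ms$rmse, tolerance = 1e-10)
    expect_lte(ms$r2, 1)
  }
  # shifting the mean predictor degrades R2 monotonically
  r2s <- vapply(c(0, 0.5, 1, 2), function(cc) {
    compute_metrics(y, rep(2 + cc, 3))$r2
  }, numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_error(compute_metrics(c(-1, 0, 1), c(0, 0, 0)), "zero test mean")
  expect_error(compute_metrics(c(2, 2, 2), c(1, 2, 3)), "zero test variance")
})

test_that("the holdout harness reproduces the 203/87 split arithmetic", {
  tbl <- generate_study(study_config(n_bands = 20, seed = 3))
  h <- repeated_holdout(tbl, "BABA", R = 2, seed = 1, a_max = 3)
  expect_equal(h$n_train, 203)
  expect_equal(h$n_test, 87)
  expect_equal(nrow(h$records), 2)
  expect_equal(unname(h$means["r2"]), mean(h$records$r2))
})

test_that("holdout evaluation is reproducible under a shared seed", {
  tbl <- small_table(n1 = 20, n2 = 20, n_bands = 25, seed = 32)
  h1 <- repeated_holdout(tbl, "Orn", R = 3, seed = 5, a_max = 5)
  h2 <- repeated_holdout(tbl, "Orn", R = 3, seed = 5, a_max = 5)
  expect_identical(h1, h2)
})

test_that("strong coupling is recovered accurately, zero coupling is not", {
  optics <- optics_config(noise_sd = 0.001)
  # zero out one weak analyte's coupling entirely
  optics$coupling["Gly", ] <- 0
  tbl <- generate_study(study_config(120, 120, n_bands = 60, seed = 33),
                        optics = optics)
  h_strong <- repeated_holdout(tbl, "BABA", R = 5, seed = 2)
  expect_gte(mean(h_strong$records$r2), 0.9)
  h_null <- repeated_holdout(tbl, "Gly", R = 5, seed = 2)
  expect_lte(mean(h_null$records$r2), 0.2)
})

test_that("variant comparison is paired, stable and honest about ties", {
  tbl <- small_table(n1 = 20, n2 = 20, n_bands = 25, seed = 34)
  all_b <- seq_along(wavelengths(tbl))
  cmp <- compare_variants(tbl, "BABA",
                          list(A = all_b, B = all_b), R = 3, seed = 6,
                          a_max = 5)
  # identical band sets give identical summaries; first label wins the tie
  expect_equal(cmp$summary$r2[1], cmp$summary$r2[2])
  expect_equal(cmp$summary$rpd[1], cmp$summary$rpd[2])
  expect_equal(cmp$winner, "A")
})

test_that("planted bands beat pure-noise bands and match all-band accuracy", {
  tbl <- study_table_60(seed = 35)
  wl <- wavelengths(tbl)
  own <- analyte_signature_centers(optics_config(), "BABA")
  planted <- unique(vapply(own, function(cn) which.min(abs(wl - cn)),
                           integer(1)))
  planted <- sort(unique(c(planted, planted + 1, planted - 1)))
  noise_bands <- which(wl > 750)[1:6]     # NIR plateau: no analyte signal
  part <- partition_bands(wl)
  cmp <- compare_variants(tbl, "BABA",
                          list(all_bands = seq_along(wl),
                               planted = planted,
                               low_range = part$low_range,
                               noise = noise_bands),
                          R = 4, seed = 7)
  s <- cmp$summary
  # the planted-band model is not meaningfully worse than all bands
  expect_gte(s$r2[s$variant == "planted"], s$r2[s$variant == "all_bands"] - 0.05)
  # a pure-noise variant never wins against the informative low range
  expect_lt(s$r2[s$variant == "noise"], s$r2[s$variant == "low_range"])
  expect_true(cmp$winner != "noise")
})

test_that("descriptive statistics reproduce the reference CV convention", {
  conc <- cbind(Gln = column_with_moments(20.93, 31.58), Flat = rep(3, 3))
  tbl <- sample_table(conc, matrix(0.3, 3, 4), c(500, 600, 700, 800))
  d <- descriptive_stats(tbl)
  expect_equal(d$cv_percent[d$analyte == "Gln"], 31.58 / 20.93 * 100,
               tolerance = 1e-10)
  expect_equal(round(d$cv_percent[d$analyte == "Gln"], 2), 150.88)
  # constant column: SD 0, CV 0
  expect_equal(d$sd[d$analyte == "Flat"], 0)
  expect_equal(d$cv_percent[d$analyte == "Flat"], 0)
  # scale invariance of CV; mean and SD double
  tbl2 <- sample_table(2 * conc, matrix(0.3, 3, 4), c(500, 600, 700, 800))
  d2 <- descriptive_stats(tbl2)
  expect_equal(d2$mean, 2 * d$mean)
  expect_equal(d2$sd, 2 * d$sd)
  expect_equal(d2$cv_percent, d$cv_percent, tolerance = 1e-10)
})
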