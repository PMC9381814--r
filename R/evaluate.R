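#' Regression evaluation metrics for a test set
#'
#' Computes the four standard calibration metrics in concentration units:
#' * `r2 = 1 - sum((yhat - y)^2) / sum((y - ybar)^2)`
#' * `rmse = sqrt(mean((y - yhat)^2))` (umol/L)
#' * `re = rmse / ybar * 100` (relative RMSE, %)
#' * `rpd = SD / rmse` (test-set sample SD over RMSE; `Inf` for a perfect
#'   fit)
#'
#' The mean and SD entering RE and RPD are those of the evaluated (test)
#' samples.
#'
#' @param y_true Measured values (umol/L), length >= 2.
#' @param y_pred Predicted values (umol/L), same length.
#' @return Object of class `metric_set`: `r2`, `rmse`, `re`, `rpd`, plus the
#'   test-set size `m`, mean `ybar` and sample SD `sd`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  m <- length(y_true)
  if (m < 2) stop2("compute_metrics: need at least 2 test samples")
  if (length(y_pred) != m) stop2("compute_metrics: length mismatch")
  ybar <- mean(y_true)
  if (ybar == 0) stop2("compute_metrics: zero test mean, RE undefined")
  s <- sd(y_true)
  if (s == 0) stop2("compute_metrics: zero test variance, RPD undefined")
  sse <- sum((y_pred - y_true)^2)
  sst <- sum((y_true - ybar)^2)
  rmse <- sqrt(sse / m)
  structure(list(
    r2 = 1 - sse / sst,
    rmse = rmse,
    re = rmse / ybar * 100,
    rpd = if (rmse == 0) Inf else s / rmse,
    m = m, ybar = ybar, sd = s
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 = %.3f  RMSE = %.3f umol/L  RE = %.2f%%  RPD = %.2f (m = %d)\n",
              x$r2, x$rmse, x$re, x$rpd, x$m))
  invisible(x)
}

## Shared split sequence so that band-set variants are compared on identical
## train/test draws. Training size is round(train_frac * n): 203 of 290.
make_splits <- function(n, R, train_frac, seed) {
  n_train <- round(train_frac * n)
  if (n_train < 3 || n - n_train < 2)
    stop2("holdout: too few samples for the requested split")
  lapply(seq_len(R), function(r) {
    set.seed(child_seed(seed, SEED_STAGE[["split"]], r))
    sort(sample.int(n, n_train))
  })
}

#' Repeated 70/30 holdout evaluation of one analyte on one band set
#'
#' Per repetition: draw a random training split, z-score the analyte on the
#' training portion, select the PLS component count by LOO PRESS on the
#' training set, fit, predict the test set, invert the z-score and compute
#' metrics in umol/L. Averages over repetitions give the reported model
#' performance; the per-repetition records are kept for stability analysis.
#'
#' @param samples A [sample_table()].
#' @param analyte Analyte name.
#' @param band_set Indices of the bands to use (default: all).
#' @param R Number of repetitions.
#' @param train_frac Training fraction (train size = `round(train_frac * n)`).
#' @param seed Integer seed; repetitions use derived child seeds.
#' @param a_max Cap on the PLS component count.
#' @param splits Optional precomputed list of training-index vectors (used by
#'   [compare_variants()] to share splits across variants).
#' @return Object of class `holdout_eval`: `records` (data.frame with one row
#'   per repetition: `rep`, `a_star`, `r2`, `rmse`, `re`, `rpd`), `means`
#'   (named vector of metric averages), `n_train`, `n_test`, `band_set`.
#' @export
repeated_holdout <- function(samples, analyte, band_set = NULL,
                             R = 100, train_frac = 0.7, seed = 1,
                             a_max = 15, splits = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  Xall <- spectra_matrix(samples)
  band_set <- band_set %||% seq_len(ncol(Xall))
  X <- Xall[, band_set, drop = FALSE]
  y <- concentration_matrix(samples)[, analyte]
  n <- nrow(X)
  splits <- splits %||% make_splits(n, R, train_frac, seed)
  stopifnot(length(splits) == R)
  rec <- vector("list", R)
  for (r in seq_len(R)) {
    tr <- splits[[r]]
    te <- setdiff(seq_len(n), tr)
    std <- standardize_fit_apply(y[tr])
    prof <- select_components(X[tr, , drop = FALSE], std$z, a_max)
    fit <- fit_pls(X[tr, , drop = FALSE], std$z, prof$a_star,
                   band_indices = band_set)
    pred <- standardize_invert(predict_pls(fit, X[te, , drop = FALSE]),
                               std$standardizer)
    met <- compute_metrics(y[te], pred)
    rec[[r]] <- data.frame(rep = r, a_star = prof$a_star, r2 = met$r2,
                           rmse = met$rmse, re = met$re, rpd = met$rpd)
  }
  records <- do.call(rbind, rec)
  means <- colMeans(records[, c("r2", "rmse", "re", "rpd")])
  structure(list(records = records, means = means,
                 n_train = length(splits[[1]]),
                 n_test = n - length(splits[[1]]),
                 band_set = band_set, analyte = analyte),
            class = "holdout_eval")
}

#' @export
print.holdout_eval <- function(x, ...) {
  cat(sprintf("Holdout evaluation of %s over %d repetitions (%d/%d split, %d bands)\n",
              x$analyte, nrow(x$records), x$n_train, x$n_test,
              length(x$band_set)))
  print(round(x$means, 4))
  invisible(x)
}

#' Compare band-set variants for one analyte and pick the best
#'
#' Evaluates each variant with [repeated_holdout()] on an identical split
#' sequence (paired comparison) and declares the winner by highest mean R2;
#' ties break by higher mean RPD, then by fewer bands, then by variant order.
#'
#' @param samples A [sample_table()].
#' @param analyte Analyte name.
#' @param variants Named list of band-index vectors.
#' @param R,train_frac,seed,a_max As in [repeated_holdout()].
#' @return Object of class `variant_comparison`: `evaluations` (named list of
#'   `holdout_eval`), `summary` (data.frame of mean metrics per variant),
#'   `winner` (variant label).
#' @export
compare_variants <- function(samples, analyte, variants, R = 100,
                             train_frac = 0.7, seed = 1, a_max = 15) {
  stopifnot(length(variants) >= 2, !is.null(names(variants)))
  n <- nrow(samples)
  splits <- make_splits(n, R, train_frac, seed)
  evs <- lapply(variants, function(bs) {
    repeated_holdout(samples, analyte, band_set = bs, R = R,
                     train_frac = train_frac, seed = seed, a_max = a_max,
                     splits = splits)
  })
  summ <- do.call(rbind, lapply(names(evs), function(nm) {
    data.frame(variant = nm, n_bands = length(evs[[nm]]$band_set),
               t(evs[[nm]]$means))
  }))
  # winner: mean R2, then RPD, then fewer bands, then listed order
  ord <- order(-summ$r2, -summ$rpd, summ$n_bands, seq_len(nrow(summ)))
  winner <- summ$variant[ord[1]]
  structure(list(evaluations = evs, summary = summ, winner = winner,
                 analyte = analyte),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Variant comparison for", x$analyte, "- winner:", x$winner, "\n")
  print(transform(x$summary, r2 = round(r2, 3), rmse = round(rmse, 3),
                  re = round(re, 2), rpd = round(rpd, 2)))
  invisible(x)
}

#' Descriptive statistics of the analyte panel
#'
#' Max, min, mean, sample SD and CV (`SD / mean x 100`, %) per analyte, the
#' layout of the reference descriptive-statistics table.
#'
#' @param samples A [sample_table()].
#' @param analytes Analyte names (default: all).
#' @return data.frame with columns `analyte`, `max`, `min`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
descriptive_stats <- function(samples, analytes = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  conc <- concentration_matrix(samples)
  if (nrow(conc) < 2) stop2("descriptive_stats: need at least 2 samples")
  analytes <- analytes %||% colnames(conc)
  conc <- conc[, analytes, drop = FALSE]
  data.frame(
    analyte = analytes,
    max = apply(conc, 2, max),
    min = apply(conc, 2, min),
    mean = colMeans(conc),
    sd = apply(conc, 2, sd),
    cv_percent = apply(conc, 2, sd) / colMeans(conc) * 100,
    row.names = NULL
  )
}
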