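#' Per-band coefficient of variation profile
#'
#' For each band, the sample (n-1) standard deviation and mean of the
#' reflectance across samples, and their ratio as a percentage
#' (`CV = SD / Mean x 100`). Bands with zero mean have an undefined CV and
#' are flagged non-finite; they are excluded from any partition statistics.
#'
#' @param X `n x b` spectra matrix, `n >= 2`.
#' @param wavelengths Band centers (nm), length `b`.
#' @return Object of class `cv_profile` (a data.frame with columns
#'   `wavelength`, `mean`, `sd`, `cv_percent`).
#' @export
band_cv_profile <- function(X, wavelengths) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop2("band_cv_profile: need at least 2 samples")
  stopifnot(ncol(X) == length(wavelengths))
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  cv <- ifelse(m == 0, NA_real_, s / m * 100)
  structure(data.frame(wavelength = as.numeric(wavelengths),
                       mean = m, sd = s, cv_percent = cv, row.names = NULL),
            class = c("cv_profile", "data.frame"))
}

#' Partition the wavelength axis at a boundary
#'
#' Deterministic split of the band indices into a low range
#' (`lambda <= boundary`) and a high range (`lambda > boundary`). The default
#' boundary, 717.08 nm, separates the visible region where leaf reflectance
#' variability is concentrated from the flat near-infrared plateau.
#'
#' @param wavelengths Ascending band centers (nm).
#' @param boundary_nm Split wavelength (nm).
#' @return Object of class `range_partition`: `boundary_nm`, `low_range`,
#'   `high_range` (index vectors).
#' @export
partition_bands <- function(wavelengths, boundary_nm = 717.08) {
  if (is.unsorted(wavelengths)) stop2("partition_bands: wavelengths must ascend")
  low <- which(wavelengths <= boundary_nm)
  high <- which(wavelengths > boundary_nm)
  if (!length(low) || !length(high))
    warning("partition_bands: boundary outside the grid; one range is empty")
  structure(list(boundary_nm = boundary_nm, low_range = low,
                 high_range = high),
            class = "range_partition")
}

#' @export
print.range_partition <- function(x, ...) {
  cat(sprintf("Range partition at %.2f nm: %d low / %d high bands\n",
              x$boundary_nm, length(x$low_range), length(x$high_range)))
  invisible(x)
}

#' Coefficient-sorted backward elimination of bands
#'
#' One repetition of the sensitive-band screening: fit a PLSR on all
#' candidate bands (component count selected by LOO PRESS), sort the bands by
#' increasing absolute regression coefficient, then remove them cumulatively
#' in that fixed order, refitting after each removal (components re-selected)
#' and recording the minimum LOO PRESS of the reduced model. The surviving
#' subset is the one attaining the smallest PRESS along the trace (ties break
#' toward the larger subset); elimination stops when `a_min_bands` bands
#' remain.
#'
#' In `"dynamic"` mode the coefficient ranking is recomputed after every
#' removal instead of being fixed once; the fixed ordering is the default.
#'
#' @param X_train `n x b` training spectra (candidate bands only), `b >= 2`.
#' @param y_train Standardized training response.
#' @param a_max Cap on the PLS component count (see [select_components()]).
#' @param a_min_bands Elimination floor (>= 2 so the coefficient ordering
#'   stays meaningful).
#' @param mode `"fixed"` (sort once) or `"dynamic"` (re-rank each step).
#' @param band_indices Indices of `X_train`'s columns within the full grid;
#'   reported results use these labels.
#' @return Object of class `band_subset_trace`: `elimination_order` (band
#'   labels sorted by increasing initial |coefficient|), `press_by_step`
#'   (PRESS after removing the first k bands, k = 0..b-a_min_bands),
#'   `best_step` (removals at the PRESS minimum) and `surviving_bands`.
#' @export
backward_elimination <- function(X_train, y_train, a_max = 15,
                                 a_min_bands = 2,
                                 mode = c("fixed", "dynamic"),
                                 band_indices = seq_len(ncol(X_train))) {
  mode <- match.arg(mode)
  X <- as.matrix(X_train)
  b <- ncol(X)
  if (b < 2) stop2("backward_elimination: need at least 2 candidate bands")
  if (a_min_bands < 2) stop2("backward_elimination: elimination floor is 2 bands")
  stopifnot(length(band_indices) == b)

  press_of <- function(cols) {
    prof <- select_components(X[, cols, drop = FALSE], y_train, a_max)
    min(prof$press)
  }
  coef_rank <- function(cols) {
    prof <- select_components(X[, cols, drop = FALSE], y_train, a_max)
    fit <- fit_pls(X[, cols, drop = FALSE], y_train, prof$a_star)
    order(abs(fit$coefficients))        # ascending |B|; stable for ties
  }

  remaining <- seq_len(b)
  elimination_order <- integer(0)
  n_steps <- b - a_min_bands
  press_by_step <- numeric(n_steps + 1)
  press_by_step[1] <- press_of(remaining)

  if (mode == "fixed") {
    ord <- coef_rank(remaining)
    elimination_order <- remaining[ord]
    for (k in seq_len(n_steps)) {
      remaining <- elimination_order[(k + 1):b]
      press_by_step[k + 1] <- press_of(remaining)
    }
  } else {
    for (k in seq_len(n_steps)) {
      drop_local <- coef_rank(remaining)[1]
      elimination_order <- c(elimination_order, remaining[drop_local])
      remaining <- remaining[-drop_local]
      press_by_step[k + 1] <- press_of(remaining)
    }
    elimination_order <- c(elimination_order, remaining)
  }

  best_step <- which.min(press_by_step) - 1L   # removals; first min = larger subset
  surviving <- elimination_order[(best_step + 1):b]
  structure(list(
    elimination_order = band_indices[elimination_order],
    press_by_step = press_by_step,
    best_step = best_step,
    surviving_bands = sort(band_indices[surviving])
  ), class = "band_subset_trace")
}

#' Vote sensitive bands over resampled repetitions
#'
#' The second screening stage: over `R` repetitions, draw a fresh random
#' training split (fraction `train_frac` of the samples), standardize the
#' analyte on the training portion, run [backward_elimination()] on the
#' candidate bands, and count each band that lands in the PRESS-minimum
#' subset. Bands surviving strictly more than `threshold` repetitions are
#' declared sensitive for that analyte (default: more than 80 of 100).
#'
#' @param samples A [sample_table()].
#' @param analyte Analyte name (column of the concentration panel).
#' @param candidate_bands Indices of the candidate bands within the full
#'   grid (typically the low range of [partition_bands()]).
#' @param R Number of repetitions.
#' @param threshold Vote cutoff (strict inequality, so `threshold = R`
#'   yields an empty sensitive set).
#' @param train_frac Training fraction per repetition.
#' @param seed Integer seed; repetitions use derived child seeds.
#' @param a_max,mode Passed to [backward_elimination()].
#' @return Object of class `frequency_table`: data.frame with columns `band`
#'   (index in the full grid), `wavelength`, `count`, `selected`; attributes
#'   `R`, `threshold`, `sensitive_bands`.
#' @export
vote_sensitive_bands <- function(samples, analyte, candidate_bands,
                                 R = 100, threshold = 80, train_frac = 0.7,
                                 seed = 1, a_max = 15,
                                 mode = c("fixed", "dynamic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(samples, "sample_table"))
  if (R < 1) stop2("vote: R must be >= 1")
  if (threshold > R) stop2("vote: threshold cannot exceed R")
  if (train_frac <= 0 || train_frac >= 1) stop2("vote: train_frac in (0,1)")
  X <- spectra_matrix(samples)[, candidate_bands, drop = FALSE]
  y <- concentration_matrix(samples)[, analyte]
  n <- nrow(X)
  n_train <- round(train_frac * n)
  if (n_train < 3 || n - n_train < 1)
    stop2("vote: too few samples for the requested split")
  count <- integer(length(candidate_bands))
  names(count) <- as.character(candidate_bands)
  for (r in seq_len(R)) {
    set.seed(child_seed(seed, SEED_STAGE[["voting"]], r))
    tr <- sample.int(n, n_train)
    ztr <- standardize_fit_apply(y[tr])$z
    trace <- backward_elimination(X[tr, , drop = FALSE], ztr, a_max = a_max,
                                  mode = mode, band_indices = candidate_bands)
    hit <- as.character(trace$surviving_bands)
    count[hit] <- count[hit] + 1L
  }
  sensitive <- candidate_bands[count > threshold]
  wl <- wavelengths(samples)[candidate_bands]
  tab <- data.frame(band = candidate_bands, wavelength = wl,
                    count = as.integer(count),
                    selected = count > threshold, row.names = NULL)
  structure(tab, R = as.integer(R), threshold = threshold,
            sensitive_bands = sensitive,
            class = c("frequency_table", "data.frame"))
}

#' Voted sensitive bands of a frequency table
#' @param x A [vote_sensitive_bands()] result.
#' @return Integer indices into the full band grid.
#' @export
sensitive_bands <- function(x) attr(x, "sensitive_bands")

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("Band frequency table: %d candidates, R = %d, threshold > %g\n",
              nrow(x), attr(x, "R"), attr(x, "threshold")))
  cat("  sensitive bands:", length(attr(x, "sensitive_bands")), "\n")
  invisible(x)
}

#' Write a frequency table as CSV
#'
#' Machine-readable form of the band-usage frequency chart: wavelength,
#' vote count and selection flag per candidate band.
#'
#' @param x A [vote_sensitive_bands()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "frequency_table"))
  df <- data.frame(wavelength_nm = x$wavelength, count = x$count,
                   selected = ifelse(x$selected, "yes", "no"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
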