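#' Configure the leaf optics of the synthetic spectral generator
#'
#' The generator builds each leaf spectrum as a smooth green-leaf baseline
#' (low visible reflectance with a green peak near 550 nm, a red edge near
#' 718 nm, and a near-infrared plateau) minus a set of Gaussian absorption
#' features whose depths are driven by the analyte concentrations. Feature
#' centers sit inside the two windows where analyte-linked spectral
#' variability concentrates in real maize leaves (505.39-604.95 nm and
#' 651.21-714.10 nm), so downstream band screening has a known ground truth
#' to recover.
#'
#' Per sample i and feature f the absorption depth is
#' `depth[i,f] = depth_scale * tanh(eta[i,f] / squash)` with
#' `eta = Z %*% coupling`, where `Z` holds column-standardized concentrations.
#' The tanh squashing keeps depths bounded (so spectra stay inside \[0,1\]
#' without clipping) while remaining strictly monotone in each coupled
#' concentration.
#'
#' @param signature_centers Wavelengths (nm) of the analyte-linked Gaussian
#'   absorption features. The default places 14 features inside the two
#'   sensitive windows: ten carried exclusively by the five
#'   strongly-expressed analytes (a pair each, one per window) and four
#'   shared by the remaining analytes.
#' @param signature_widths Gaussian sigma (nm) per feature; positive.
#' @param coupling Numeric matrix, analytes x features: loading of each
#'   standardized concentration on each feature depth. Default:
#'   [default_coupling()] (only available for the default 14-feature
#'   layout; custom centers require an explicit coupling matrix).
#' @param depth_scale Maximum absorption depth per feature (reflectance
#'   units).
#' @param squash Scale of the tanh saturation applied to the coupled
#'   standardized concentrations (unitless).
#' @param noise_sd Additive per-band reflectance noise SD.
#' @param multiplicative_sd SD of the per-sample multiplicative gain
#'   (gain ~ 1 + N(0, multiplicative_sd)).
#' @param baseline Optional explicit baseline reflectance vector (one value
#'   per band of the wavelength grid in use). When `NULL` the parametric
#'   green-leaf baseline is evaluated on whatever grid is requested.
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(signature_centers = default_signature_centers(),
                          signature_widths = 5,
                          coupling = NULL,
                          depth_scale = 0.04,
                          squash = 3,
                          noise_sd = 0.002,
                          multiplicative_sd = 0.005,
                          baseline = NULL) {
  if (length(signature_widths) == 1L)
    signature_widths <- rep(signature_widths, length(signature_centers))
  if (length(signature_centers) != length(signature_widths))
    stop2("optics: centers and widths must have equal length")
  if (any(signature_widths <= 0)) stop2("optics: signature widths must be > 0")
  if (is.null(coupling)) {
    if (length(signature_centers) != 14L)
      stop2("optics: default coupling needs the 14-feature default layout; ",
            "supply a coupling matrix for custom centers")
    coupling <- default_coupling()
  }
  coupling <- as.matrix(coupling)
  if (ncol(coupling) != length(signature_centers))
    stop2("optics: coupling must have one column per signature feature")
  if (!is.null(baseline) && (any(baseline < 0) || any(baseline > 1)))
    stop2("optics: baseline reflectance must lie in [0, 1]")
  if (noise_sd < 0 || multiplicative_sd < 0)
    stop2("optics: noise SDs must be non-negative")
  structure(list(signature_centers = signature_centers,
                 signature_widths = signature_widths,
                 coupling = coupling,
                 depth_scale = depth_scale,
                 squash = squash,
                 noise_sd = noise_sd,
                 multiplicative_sd = multiplicative_sd,
                 baseline = baseline),
            class = "optics_config")
}

#' Default signature feature centers
#'
#' Fourteen feature wavelengths (nm) inside the two sensitive windows
#' (505.39-604.95 and 651.21-714.10 nm): eight in the green/yellow window,
#' six in the red window, spaced so that neighboring features remain
#' spectrally resolvable.
#'
#' @return Numeric vector of length 14.
#' @export
default_signature_centers <- function() {
  c(511.9, 522.0, 532.2, 552.5, 562.7, 583.1, 593.2, 603.4,   # 505-605 window
    654.2, 664.4, 674.6, 684.7, 694.9, 705.1)                 # 651-714 window
}

## Feature roles within the default layout: the five strongly-expressed
## analytes carry exclusive feature pairs (one per window); the remaining
## features form the shared pool for the weak analytes.
STRONG_FEATURES <- list(
  BABA = c(4, 12), Orn = c(2, 14), Cit = c(6, 9), Met = c(1, 11),
  His = c(8, 13)
)
SHARED_FEATURES <- c(3, 5, 7, 10)

#' Default analyte-to-feature coupling matrix
#'
#' Builds the 24 x 14 loading matrix tying standardized analyte
#' concentrations to absorption-feature depths, emulating the accuracy
#' structure observed on real leaves. The first five panel analytes (the
#' ones whose published models are most accurate) each own an exclusive pair
#' of features, one per sensitive window, with strong loadings; the
#' remaining nineteen analytes load on a single feature from a shared pool
#' of four, with strictly decreasing strengths, assigned greedily to the
#' shared feature with the smallest accumulated squared loading so that
#' per-feature interference stays balanced. With exclusive features an
#' analyte's recoverability is then a monotone function of its own coupling
#' strength (row norm, see [coupling_strength()]).
#'
#' @param n_analytes Number of analytes (>= 5; default 24).
#' @return Numeric matrix `n_analytes x 14`.
#' @export
default_coupling <- function(n_analytes = 24) {
  if (n_analytes < 5) stop2("default_coupling: need at least 5 analytes")
  C <- matrix(0, n_analytes, 14)
  strong_load <- rbind(c(1.00, 0.80), c(0.95, 0.75), c(0.90, 0.70),
                       c(0.85, 0.65), c(0.80, 0.60))
  for (j in 1:5) C[j, STRONG_FEATURES[[j]]] <- strong_load[j, ]
  rest <- setdiff(seq_len(n_analytes), 1:5)
  if (length(rest)) {
    s <- seq(0.52, 0.10, length.out = length(rest))
    power <- numeric(length(SHARED_FEATURES))
    for (k in seq_along(rest)) {
      f <- which.min(power)
      C[rest[k], SHARED_FEATURES[f]] <- s[k]
      power[f] <- power[f] + s[k]^2
    }
  }
  if (n_analytes == 24) rownames(C) <- amino_acid_reference()$analyte
  C
}

#' Signature centers coupled to one analyte
#'
#' Ground-truth helper: the wavelengths of the absorption features an
#' analyte loads on (above a minimum absolute loading), used to judge
#' whether band screening recovered the planted signal.
#'
#' @param optics An [optics_config()].
#' @param analyte Row index or name of the coupling matrix.
#' @param min_loading Loadings at or below this are ignored.
#' @return Numeric vector of wavelengths (nm).
#' @export
analyte_signature_centers <- function(optics, analyte, min_loading = 0.05) {
  stopifnot(inherits(optics, "optics_config"))
  row <- optics$coupling[analyte, ]
  optics$signature_centers[abs(row) > min_loading]
}

#' Per-analyte coupling strength of an optics configuration
#'
#' The Euclidean norm of each analyte's row of the coupling matrix: the
#' generator's ground-truth measure of how strongly an analyte is expressed
#' in the spectra, used by the evaluation harness to check that estimation
#' accuracy tracks planted signal strength.
#'
#' @param optics An [optics_config()].
#' @return Named numeric vector (names attached when the coupling rows are
#'   named).
#' @export
coupling_strength <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  sqrt(rowSums(optics$coupling^2))
}

#' Green-leaf baseline reflectance on a wavelength grid
#'
#' Parametric baseline used by the generator when no explicit baseline vector
#' is supplied: a low visible floor with a Gaussian green peak at 550 nm, a
#' logistic red edge centered at 718 nm, and a near-infrared plateau.
#'
#' @param wavelengths Ascending wavelength grid (nm).
#' @param optics An [optics_config()]; if it carries an explicit `baseline`
#'   vector of matching length that vector is returned.
#' @return Reflectance vector in \[0, 1\].
#' @export
baseline_spectrum <- function(wavelengths, optics = optics_config()) {
  if (!is.null(optics$baseline)) {
    if (length(optics$baseline) != length(wavelengths))
      stop2("optics: explicit baseline length does not match wavelength grid")
    return(optics$baseline)
  }
  vis <- 0.06 + 0.10 * exp(-(wavelengths - 550)^2 / (2 * 45^2))
  edge <- stats::plogis((wavelengths - 718) / 10)
  vis + (0.48 - vis) * edge
}

#' Configure the synthetic study layout
#'
#' Sample counts mirror the two nitrogen-treatment experiments of the
#' emulated study (144 + 146 leaf samples) and the imaging spectrometer's
#' 300 channels over 400-1000 nm.
#'
#' @param n_exp1,n_exp2 Sample counts of the two experiments.
#' @param n_bands Number of spectral channels.
#' @param wl_min,wl_max Wavelength grid endpoints (nm).
#' @param cube_shape Integer (rows, cols) used when rendering per-sample
#'   image cubes.
#' @param seed Master seed for the study.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_exp1 = 144, n_exp2 = 146, n_bands = 300,
                         wl_min = 400, wl_max = 1000,
                         cube_shape = c(16, 16), seed = 1) {
  if (n_exp1 + n_exp2 < 2) stop2("study: need at least 2 samples in total")
  if (n_bands < 10) stop2("study: need at least 10 bands")
  if (wl_min >= wl_max) stop2("study: wl_min must be below wl_max")
  structure(list(n_exp1 = as.integer(n_exp1), n_exp2 = as.integer(n_exp2),
                 n_bands = as.integer(n_bands), wl_min = wl_min,
                 wl_max = wl_max, cube_shape = as.integer(cube_shape),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Wavelength grid of a study configuration
#' @param study A [study_config()].
#' @return Ascending numeric vector of band centers (nm).
#' @export
study_grid <- function(study) {
  seq(study$wl_min, study$wl_max, length.out = study$n_bands)
}

#' Draw a synthetic analyte concentration table
#'
#' Concentrations are log-normal, moment-matched per analyte to the panel's
#' target mean and SD (`sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2/2`), then truncated below at `min_clip`.
#' Draws use stratified uniforms (one per equal-probability stratum, in
#' random order) pushed through the log-normal quantile function, so sample
#' moments converge to the targets quickly even for the heavy-tailed
#' high-CV analytes while the marginal distribution stays log-normal.
#'
#' @param n Number of samples (rows).
#' @param panel An [analyte_panel_config()].
#' @param seed Integer seed.
#' @return `n x k` numeric matrix (umol/L), columns named by analyte.
#' @export
generate_concentrations <- function(n, panel = analyte_panel_config(),
                                    seed = 1) {
  stopifnot(inherits(panel, "analyte_panel_config"))
  if (n < 1) stop2("generate_concentrations: n must be >= 1")
  k <- length(panel$names)
  set.seed(child_seed(seed, SEED_STAGE[["concentrations"]]))
  out <- matrix(0, n, k, dimnames = list(NULL, panel$names))
  for (j in seq_len(k)) {
    m <- panel$mean[j]; s <- panel$sd[j]
    if (s == 0) { out[, j] <- pmax(m, panel$min_clip[j]); next }
    sdlog2 <- log(1 + (s / m)^2)
    meanlog <- log(m) - sdlog2 / 2
    u <- (sample.int(n) - 1 + runif(n)) / n   # stratified uniforms
    out[, j] <- pmax(qlnorm(u, meanlog, sqrt(sdlog2)), panel$min_clip[j])
  }
  out
}

#' Generate leaf reflectance spectra from a concentration table
#'
#' Each spectrum is
#' `clip(gain_i * (baseline - rowSums(depth_i,f * Gauss_f)) + noise, 0, 1)`
#' with depths a bounded monotone map of the standardized concentrations
#' through the coupling matrix (see [optics_config()]). Columns of the
#' concentration table are standardized by their own sample mean and SD
#' (constant columns map to zero).
#'
#' @param concentrations `n x k` matrix (umol/L).
#' @param optics An [optics_config()]; its coupling matrix must have `k` rows.
#' @param wavelengths Ascending wavelength grid (nm).
#' @param seed Integer seed (noise draws).
#' @return `n x bands` reflectance matrix in \[0, 1\].
#' @export
generate_reflectance <- function(concentrations, optics = optics_config(),
                                 wavelengths, seed = 1) {
  stopifnot(inherits(optics, "optics_config"))
  X <- as.matrix(concentrations)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop2("generate_reflectance: wavelengths must be strictly ascending")
  if (nrow(optics$coupling) != ncol(X))
    stop2("generate_reflectance: coupling matrix must have one row per analyte")
  n <- nrow(X); b <- length(wavelengths)
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- Inf          # constant analytes contribute 0
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  eta <- Z %*% optics$coupling                 # n x F
  depth <- optics$depth_scale * tanh(eta / optics$squash)
  G <- vapply(seq_along(optics$signature_centers), function(f) {
    exp(-(wavelengths - optics$signature_centers[f])^2 /
          (2 * optics$signature_widths[f]^2))
  }, numeric(b))                               # bands x F
  base <- baseline_spectrum(wavelengths, optics)
  raw <- matrix(base, n, b, byrow = TRUE) - depth %*% t(G)
  set.seed(child_seed(seed, SEED_STAGE[["reflectance"]]))
  gain <- 1 + rnorm(n, 0, optics$multiplicative_sd)
  raw <- raw * gain
  if (optics$noise_sd > 0)
    raw <- raw + matrix(rnorm(n * b, 0, optics$noise_sd), n, b)
  out <- pmin(pmax(raw, 0), 1)
  if (all(out == 0 | out == 1))
    stop2("generate_reflectance: degenerate optics, all reflectance clipped")
  out
}

#' Render a single-leaf hyperspectral image cube
#'
#' Places the supplied leaf spectrum on an elliptical leaf region (plus
#' optional per-pixel noise) over a background whose reflectance decreases
#' strictly with wavelength, so that background NDVI is negative by
#' construction and NDVI > 0 segmentation recovers the leaf mask exactly in
#' the noise-free case.
#'
#' @param spectrum Leaf reflectance vector (one value per band, in \[0,1\]).
#' @param wavelengths Ascending band centers (nm), same length as `spectrum`.
#' @param shape Integer (rows, cols); both must be >= 8.
#' @param seed Integer seed for per-pixel noise.
#' @param pixel_noise_sd Additive per-pixel reflectance noise SD.
#' @param background Reflectance of the background at the first and last
#'   band; interpolated linearly (and strictly decreasing) in between.
#' @return A list with `cube` (a [hyperspectral_cube()]) and `leaf_mask`
#'   (logical rows x cols matrix, the ground truth).
#' @export
generate_cube <- function(spectrum, wavelengths, shape = c(16, 16), seed = 1,
                          pixel_noise_sd = 0.003,
                          background = c(0.40, 0.10)) {
  if (length(shape) != 2L || any(shape < 8))
    stop2("generate_cube: shape must be (rows, cols) with both >= 8")
  b <- length(spectrum)
  stopifnot(length(wavelengths) == b)
  if (background[2] >= background[1])
    stop2("generate_cube: background must decrease with wavelength")
  rows <- shape[1]; cols <- shape[2]
  rc <- (rows + 1) / 2; cc <- (cols + 1) / 2
  ra <- 0.38 * rows; ca <- 0.38 * cols
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  mask <- ((rr - rc) / ra)^2 + ((cm - cc) / ca)^2 <= 1
  bg <- background[1] + (background[2] - background[1]) *
    (wavelengths - wavelengths[1]) / (wavelengths[b] - wavelengths[1])
  flat <- matrix(bg, rows * cols, b, byrow = TRUE)
  flat[as.vector(mask), ] <- matrix(spectrum, sum(mask), b, byrow = TRUE)
  if (pixel_noise_sd > 0) {
    set.seed(child_seed(seed, SEED_STAGE[["cube"]]))
    flat <- flat + matrix(rnorm(length(flat), 0, pixel_noise_sd),
                          nrow(flat), ncol(flat))
    flat <- pmin(pmax(flat, 0), 1)
  }
  cube <- hyperspectral_cube(array(flat, c(rows, cols, b)), wavelengths)
  list(cube = cube, leaf_mask = mask)
}

#' Generate a complete synthetic study
#'
#' Draws the concentration panel, generates the matching leaf spectra, and
#' assembles the central exchange object of the workflow: a sample table with
#' one row per leaf carrying the experiment label, the 24 analyte
#' concentrations and the mean leaf spectrum.
#'
#' @param study A [study_config()].
#' @param panel An [analyte_panel_config()].
#' @param optics An [optics_config()].
#' @return A [sample_table()] with `n_exp1 + n_exp2` rows.
#' @export
generate_study <- function(study = study_config(),
                           panel = analyte_panel_config(),
                           optics = optics_config()) {
  stopifnot(inherits(study, "study_config"))
  n <- study$n_exp1 + study$n_exp2
  conc <- generate_concentrations(n, panel, seed = study$seed)
  grid <- study_grid(study)
  spec <- generate_reflectance(conc, optics, grid, seed = study$seed)
  sample_table(
    concentrations = conc,
    spectra = spec,
    wavelengths = grid,
    experiment = rep(c(1L, 2L), c(study$n_exp1, study$n_exp2))
  )
}

#' Sample table: the workflow's central exchange object
#'
#' One row per leaf sample: identifier, experiment of origin, the analyte
#' concentrations (umol/L) and the mean leaf reflectance per band. Stored as
#' a data.frame with wavelength-named spectral columns so it round-trips
#' through CSV; accessor helpers return the numeric matrices.
#'
#' @param concentrations `n x k` matrix, columns named by analyte.
#' @param spectra `n x bands` reflectance matrix.
#' @param wavelengths Band centers (nm).
#' @param experiment Integer vector of experiment labels (length n).
#' @param sample_id Optional identifiers; default `S001...`.
#' @return Object of class `sample_table` (inherits data.frame).
#' @export
sample_table <- function(concentrations, spectra, wavelengths,
                         experiment = rep(1L, nrow(concentrations)),
                         sample_id = NULL) {
  conc <- as.matrix(concentrations)
  spec <- as.matrix(spectra)
  stopifnot(nrow(conc) == nrow(spec), ncol(spec) == length(wavelengths))
  n <- nrow(conc)
  sample_id <- sample_id %||% sprintf("S%03d", seq_len(n))
  analytes <- colnames(conc)
  if (is.null(analytes)) analytes <- sprintf("A%02d", seq_len(ncol(conc)))
  df <- data.frame(sample_id = sample_id, experiment = as.integer(experiment),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df[analytes] <- as.data.frame(conc)
  wl_names <- format_wavelength(wavelengths)
  df[wl_names] <- as.data.frame(spec)
  structure(df, analytes = analytes, wavelengths = as.numeric(wavelengths),
            class = c("sample_table", "data.frame"))
}

format_wavelength <- function(wl) sprintf("%.3f", wl)

#' @export
print.sample_table <- function(x, ...) {
  cat("Sample table:", nrow(x), "samples,", length(attr(x, "analytes")),
      "analytes,", length(attr(x, "wavelengths")), "bands (",
      format(min(attr(x, "wavelengths"))), "-",
      format(max(attr(x, "wavelengths"))), "nm )\n")
  cat("  experiments:", paste(sprintf("%d x exp%s", table(x$experiment),
                                      names(table(x$experiment))),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Extract the spectra matrix of a sample table
#' @param x A [sample_table()].
#' @return `n x bands` numeric matrix.
#' @export
spectra_matrix <- function(x) {
  stopifnot(inherits(x, "sample_table"))
  as.matrix(x[, format_wavelength(attr(x, "wavelengths")), drop = FALSE])
}

#' Extract the concentration matrix of a sample table
#' @param x A [sample_table()].
#' @return `n x k` numeric matrix (umol/L), columns named by analyte.
#' @export
concentration_matrix <- function(x) {
  stopifnot(inherits(x, "sample_table"))
  as.matrix(x[, attr(x, "analytes"), drop = FALSE])
}

#' Band centers of a spectral object
#' @param x A [sample_table()] or [hyperspectral_cube()].
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(x) UseMethod("wavelengths")

#' @export
wavelengths.sample_table <- function(x) attr(x, "wavelengths")

#' Analyte labels of a sample table
#' @param x A [sample_table()].
#' @return Character vector.
#' @export
analyte_names <- function(x) attr(x, "analytes")

#' Write / read a sample table as CSV
#'
#' Column layout: `sample_id`, `experiment`, one column per analyte, then one
#' column per band named by its wavelength in nm.
#'
#' @param x A [sample_table()].
#' @param path CSV file path.
#' @return `write_sample_table` returns `path` invisibly;
#'   `read_sample_table` returns a [sample_table()].
#' @export
write_sample_table <- function(x, path) {
  stopifnot(inherits(x, "sample_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)
  wl_cols <- cols[grepl("^[0-9]+(\\.[0-9]+)?$", cols)]
  analytes <- setdiff(cols, c("sample_id", "experiment", wl_cols))
  sample_table(
    concentrations = as.matrix(df[analytes]),
    spectra = as.matrix(df[wl_cols]),
    wavelengths = as.numeric(wl_cols),
    experiment = df$experiment,
    sample_id = df$sample_id
  )
}
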