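#' Savitzky-Golay smoothing of spectra
#'
#' Local least-squares polynomial smoothing applied independently to each
#' row (spectrum). Endpoints are handled with the off-center polynomial
#' filters, so the band axis keeps its full length and stays aligned with the
#' wavelength grid (required downstream, where band indices are voted on).
#' Any polynomial of degree <= `polyorder` is reproduced exactly.
#'
#' Defaults (window 11 channels, order 2) are a common chemometrics choice at
#' ~2 nm resolution; on coarser grids the window should be narrowed so it
#' does not span real spectral features.
#'
#' @param spectra `n x bands` matrix (or a single spectrum vector).
#' @param window_length Odd integer, number of channels in the fitting
#'   window; must not exceed the number of bands.
#' @param polyorder Polynomial degree; must be < `window_length`.
#' @return Smoothed matrix (or vector) of the same shape.
#' @export
savgol_smooth <- function(spectra, window_length = 11, polyorder = 2) {
  if (window_length %% 2 == 0)
    stop2("savgol: window_length must be odd")
  if (polyorder >= window_length)
    stop2("savgol: polyorder must be smaller than window_length")
  vec_in <- is.null(dim(spectra))
  X <- if (vec_in) matrix(spectra, 1) else as.matrix(spectra)
  if (ncol(X) < window_length)
    stop2("savgol: window_length exceeds the number of bands")
  out <- t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window_length))
  if (vec_in) drop(out) else out
}

#' Fit and apply z-score standardization
#'
#' Amino acid contents span two orders of magnitude across analytes, so each
#' response is centered and scaled to unit variance before PLSR. The sample
#' (n-1) SD convention is used, matching the convention of the reference
#' descriptive statistics. The returned standardizer must be fitted on the
#' training portion only and carried along to invert test-set predictions
#' back to umol/L.
#'
#' @param y Numeric vector of concentrations (umol/L), length >= 2.
#' @return List with `z` (standardized vector, mean 0 / SD 1) and
#'   `standardizer` (class `standardizer`: fields `mean`, `sd`).
#' @export
standardize_fit_apply <- function(y) {
  if (length(y) < 2) stop2("standardize: need at least 2 values")
  m <- mean(y)
  s <- sd(y)
  if (s == 0) stop2("standardize: zero-variance response")
  list(z = (y - m) / s,
       standardizer = structure(list(mean = m, sd = s), class = "standardizer"))
}

#' Invert a z-score standardization
#'
#' Maps standardized predictions back to concentration units:
#' `z * sd + mean`. Round trip with [standardize_fit_apply()] is the
#' identity.
#'
#' @param z Numeric vector in standardized units.
#' @param s A `standardizer` (from [standardize_fit_apply()]).
#' @return Numeric vector in umol/L.
#' @export
standardize_invert <- function(z, s) {
  stopifnot(inherits(s, "standardizer"))
  z * s$sd + s$mean
}
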