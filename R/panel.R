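#' Reference descriptive statistics for 24 amino acids in fresh maize leaves
#'
#' Published descriptive statistics (max, min, mean, SD, coefficient of
#' variation, all concentrations in umol/L) for the 24 free amino acids
#' quantified by LC-MS in fresh maize leaves across two nitrogen-treatment
#' experiments (290 leaf samples in total). The table serves two purposes:
#' it is the calibration target for the synthetic concentration generator
#' ([analyte_panel_config()] takes its Mean/SD columns as defaults), and it is
#' the fixture for the descriptive-statistics reproduction checks (the printed
#' CV column must be recoverable as SD/Mean x 100 to within rounding).
#'
#' Rows are ordered by decreasing published estimation accuracy of the
#' corresponding all-band PLSR model (beta-aminobutyric acid first), which is
#' also the order in which the synthetic generator assigns coupling strengths.
#'
#' @return A data.frame with columns `analyte`, `max`, `min`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
amino_acid_reference <- function() {
  df <- data.frame(
    analyte = c("BABA", "Orn", "Cit", "Met", "His", "Sar", "Ala", "Glu",
                "Pro", "Thr", "Asp", "Leu", "Ile", "GABA", "Arg", "Tyr",
                "Gln", "Asn", "Val", "Lys", "Phe", "Trp", "Ser", "Gly"),
    max  = c(64.08, 11.24, 16.51, 10.55, 34.40, 788.29, 770.64, 678.80,
             52.69, 131.36, 207.79, 72.26, 66.41, 51.17, 19.55, 40.10,
             224.48, 167.89, 112.95, 101.42, 48.76, 51.27, 622.39, 520.43),
    min  = c(0.06, 0.49, 0.04, 0.03, 0.39, 3.75, 3.75, 3.25,
             1.06, 0.88, 4.27, 2.23, 0.06, 0.06, 2.98, 2.46,
             0.09, 0.03, 4.29, 0.99, 2.11, 1.30, 1.55, 3.48),
    mean = c(7.00, 5.55, 4.91, 4.20, 6.49, 149.96, 145.37, 166.38,
             10.14, 21.71, 41.14, 12.92, 8.16, 10.00, 7.94, 9.86,
             20.93, 13.11, 19.28, 13.80, 9.87, 8.69, 63.71, 35.23),
    sd   = c(6.60, 4.40, 3.85, 3.05, 4.56, 134.36, 126.77, 113.28,
             6.82, 15.35, 28.85, 8.71, 7.41, 8.06, 3.73, 5.97,
             31.58, 20.83, 13.27, 7.22, 5.10, 6.90, 87.94, 51.36),
    cv_percent = c(94.29, 79.28, 78.41, 72.62, 70.26, 89.60, 87.21, 68.09,
                   67.26, 70.70, 70.13, 67.41, 90.81, 80.60, 46.98, 60.55,
                   150.88, 158.89, 68.83, 52.32, 51.67, 79.40, 138.03, 145.78),
    stringsAsFactors = FALSE
  )
  df
}

#' Configure the analyte concentration panel
#'
#' Describes the marginal distribution targets for the 24-analyte
#' concentration panel the synthetic generator draws from: per-analyte target
#' mean and SD (umol/L) and a lower truncation bound. Defaults come from the
#' reference descriptive statistics of fresh maize leaves
#' ([amino_acid_reference()]).
#'
#' @param names Character vector of analyte labels (24 by default).
#' @param mean Numeric vector of target means, umol/L; must be positive.
#' @param sd Numeric vector of target standard deviations, umol/L;
#'   non-negative.
#' @param min_clip Lower truncation bound, umol/L (single value or
#'   per-analyte); non-negative. Defaults to 0 (log-normal draws are already
#'   strictly positive).
#' @return An object of class `analyte_panel_config`.
#' @export
analyte_panel_config <- function(names = NULL, mean = NULL, sd = NULL,
                                 min_clip = 0) {
  ref <- amino_acid_reference()
  names <- names %||% ref$analyte
  mean <- mean %||% ref$mean[match(names, ref$analyte)]
  sd <- sd %||% ref$sd[match(names, ref$analyte)]
  k <- length(names)
  if (length(mean) != k || length(sd) != k)
    stop2("panel: names, mean and sd must have equal length")
  if (anyNA(mean) || any(mean <= 0))
    stop2("panel: target means must be positive")
  if (anyNA(sd) || any(sd < 0))
    stop2("panel: target SDs must be non-negative")
  min_clip <- rep_len(min_clip, k)
  if (any(min_clip < 0)) stop2("panel: min_clip must be non-negative")
  structure(list(names = as.character(names), mean = as.numeric(mean),
                 sd = as.numeric(sd), min_clip = as.numeric(min_clip)),
            class = "analyte_panel_config")
}

#' @export
print.analyte_panel_config <- function(x, ...) {
  cat("Analyte panel:", length(x$names), "analytes\n")
  cat("  mean range:", format(min(x$mean)), "-", format(max(x$mean)), "umol/L\n")
  cat("  CV range:", sprintf("%.1f", min(100 * x$sd / x$mean)), "-",
      sprintf("%.1f", max(100 * x$sd / x$mean)), "%\n")
  invisible(x)
}
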