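## Second screening stage: per-analyte coefficient-sorted backward
## elimination with frequency voting over resampled repetitions, run on the
## low (visible) range found in 03. Voting is scaled to R = 20 repetitions
## with a proportional >16 threshold (the full protocol uses 100 and >80).

source("analysis/00_common.R")

tbl <- smoothed_study()
wl <- wavelengths(tbl)
part <- partition_bands(wl)
optics <- optics_config()

R_VOTE <- 20
THRESHOLD <- 16

sets <- list()
for (a in analyte_names(tbl)) {
  ft <- vote_sensitive_bands(tbl, a, part$low_range, R = R_VOTE,
                             threshold = THRESHOLD, seed = STUDY_SEED)
  write_frequency_table(ft, file.path(RESULTS_DIR,
                                      paste0("frequency_", a, ".csv")))
  sb <- sensitive_bands(ft)
  sets[[a]] <- sb
  own <- analyte_signature_centers(optics, a)
  hit <- if (length(sb) && length(own))
    sum(vapply(own, function(cn) min(abs(wl[sb] - cn)) <= 5, logical(1)))
  else 0L
  cat(sprintf("%-5s %2d sensitive band(s): %-38s [%d/%d planted centers hit]\n",
              a, length(sb),
              paste(sprintf("%.0f", wl[sb]), collapse = " "),
              hit, length(own)))
}

long <- do.call(rbind, lapply(names(sets), function(a) {
  if (!length(sets[[a]])) return(NULL)
  data.frame(analyte = a, band = sets[[a]], wavelength = wl[sets[[a]]])
}))
write.csv(long, file.path(RESULTS_DIR, "sensitive_sets.csv"),
          row.names = FALSE)
cat("Wrote per-analyte frequency tables and",
    file.path(RESULTS_DIR, "sensitive_sets.csv"), "\n")
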