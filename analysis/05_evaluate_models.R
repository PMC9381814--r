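## Repeated 70/30 holdout evaluation of every analyte on the four band-set
## variants: all bands, the low (visible) range, the high (NIR) range, and
## the voted sensitive bands from 04. R = 10 repetitions at desk scale (the
## full protocol uses 100); splits are shared across variants through the
## common seed, so the comparison is paired.

source("analysis/00_common.R")

tbl <- smoothed_study()
wl <- wavelengths(tbl)
part <- partition_bands(wl)

sens_path <- file.path(RESULTS_DIR, "sensitive_sets.csv")
if (!file.exists(sens_path))
  stop("run analysis/04_screen_sensitive_bands.R first")
sens <- read.csv(sens_path)

R_EVAL <- 10
variants <- list(all_bands = seq_along(wl),
                 low_range = part$low_range,
                 high_range = part$high_range)

for (vn in names(variants)) {
  rows <- lapply(analyte_names(tbl), function(a) {
    h <- repeated_holdout(tbl, a, variants[[vn]], R = R_EVAL,
                          seed = STUDY_SEED)
    data.frame(analyte = a, t(h$means), n_bands = length(variants[[vn]]))
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(RESULTS_DIR, paste0("evaluation_", vn, ".csv")),
            row.names = FALSE)
  cat(sprintf("%-10s best analyte: %s (R2 = %.2f)\n", vn,
              tab$analyte[which.max(tab$r2)], max(tab$r2)))
}

rows <- lapply(analyte_names(tbl), function(a) {
  bs <- sens$band[sens$analyte == a]
  if (length(bs) >= 1) {
    h <- repeated_holdout(tbl, a, bs, R = R_EVAL, seed = STUDY_SEED)
    data.frame(analyte = a, t(h$means), n_bands = length(bs))
  } else {
    data.frame(analyte = a, r2 = NA, rmse = NA, re = NA, rpd = NA,
               n_bands = 0L)
  }
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(RESULTS_DIR, "evaluation_sensitive_bands.csv"),
          row.names = FALSE)
cat(sprintf("sensitive   best analyte: %s (R2 = %.2f, %d bands)\n",
            tab$analyte[which.max(tab$r2)], max(tab$r2, na.rm = TRUE),
            tab$n_bands[which.max(tab$r2)]))
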