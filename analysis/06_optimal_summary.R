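## Pick the optimal band-set variant per analyte (highest mean R2, ties by
## RPD then by fewer bands) and export measured-vs-predicted scatter data
## for the winning models.

source("analysis/00_common.R")

tbl <- smoothed_study()
wl <- wavelengths(tbl)
part <- partition_bands(wl)

read_eval <- function(vn) {
  f <- file.path(RESULTS_DIR, paste0("evaluation_", vn, ".csv"))
  if (!file.exists(f)) stop("run analysis/05_evaluate_models.R first")
  cbind(variant = vn, read.csv(f))
}
variants <- c("all_bands", "low_range", "high_range", "sensitive_bands")
evals <- do.call(rbind, lapply(variants, read_eval))
sens <- read.csv(file.path(RESULTS_DIR, "sensitive_sets.csv"))

band_set_of <- function(vn, a) switch(vn,
  all_bands = seq_along(wl),
  low_range = part$low_range,
  high_range = part$high_range,
  sensitive_bands = sens$band[sens$analyte == a])

optimal <- do.call(rbind, lapply(unique(evals$analyte), function(a) {
  cand <- evals[evals$analyte == a & !is.na(evals$r2), ]
  ord <- order(-cand$r2, -cand$rpd, cand$n_bands)
  cand[ord[1], ]
}))
write.csv(optimal, file.path(RESULTS_DIR, "optimal_models.csv"),
          row.names = FALSE)

cat("Optimal model per analyte (top 8 by R2):\n")
top <- optimal[order(-optimal$r2), ][1:8, ]
print(data.frame(analyte = top$analyte, variant = top$variant,
                 r2 = round(top$r2, 2), rmse = round(top$rmse, 2),
                 re = round(top$re, 1), rpd = round(top$rpd, 2),
                 row.names = NULL))
cat(sprintf("%d of %d analytes are best served by a reduced band set\n",
            sum(optimal$variant != "all_bands"), nrow(optimal)))

scatter <- do.call(rbind, lapply(top$analyte[1:4], function(a) {
  vn <- optimal$variant[optimal$analyte == a]
  holdout_predictions(tbl, a, band_set_of(vn, a), 0.7, STUDY_SEED, 15)
}))
write.csv(scatter, file.path(RESULTS_DIR, "scatter_optimal.csv"),
          row.names = FALSE)
cat("Wrote", file.path(RESULTS_DIR, "optimal_models.csv"), "and",
    file.path(RESULTS_DIR, "scatter_optimal.csv"), "\n")
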