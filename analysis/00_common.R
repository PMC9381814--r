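## Shared settings for the analysis scripts.
##
## The study is simulated at a reduced desk scale (60 bands instead of 300)
## so the whole workflow, including the band-elimination voting, runs in
## minutes; the algorithms are identical at full scale, only the band count
## changes. Every script regenerates the study deterministically from
## STUDY_SEED instead of passing large tables around.

library(aminospec)

STUDY_SEED <- 20
N_BANDS <- 60
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

load_study <- function() {
  generate_study(study_config(n_bands = N_BANDS, seed = STUDY_SEED))
}

## Savitzky-Golay smoothing at a window suited to the reduced grid (5
## channels of ~10 nm; the full-resolution default of 11 channels would span
## real spectral features here).
smoothed_study <- function(tbl = load_study()) {
  sample_table(concentration_matrix(tbl),
               savgol_smooth(spectra_matrix(tbl), 5, 2),
               wavelengths(tbl), experiment = tbl$experiment,
               sample_id = tbl$sample_id)
}
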