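default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "results",
    generator = list(
      enabled = TRUE,
      n_exp1 = 144L, n_exp2 = 146L,
      n_bands = 300L, wl_min = 400, wl_max = 1000,
      noise_sd = 0.002, multiplicative_sd = 0.005,
      use_cubes = FALSE, cube_shape = c(16L, 16L), pixel_noise_sd = 0
    ),
    data = list(path = NULL),
    smoothing = list(enabled = TRUE, window_length = 11L, polyorder = 2L),
    selection = list(R = 100L, threshold = 80, boundary_nm = 717.08,
                     mode = "fixed", a_max = 15L, analytes = NULL),
    evaluation = list(R = 100L, train_frac = 0.7, a_max = 15L)
  )
}

merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop2("config: '", paste(path, collapse = "."),
                            "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop2("config: unknown key(s): ",
          paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or accepts an R list), fills every missing key with its
#' default, rejects unknown keys, and checks cross-field constraints
#' (vote threshold below the repetition count, odd smoothing window, valid
#' training fraction, generator or data path present).
#'
#' @param config Path to a YAML file, a list, or `NULL` (all defaults).
#' @return A normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config: file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (cfg$selection$threshold >= cfg$selection$R)
    stop2("config: selection.threshold must be smaller than selection.R")
  if (cfg$smoothing$enabled && cfg$smoothing$window_length %% 2 == 0)
    stop2("config: smoothing.window_length must be odd")
  if (cfg$smoothing$enabled && cfg$smoothing$polyorder >= cfg$smoothing$window_length)
    stop2("config: smoothing.polyorder must be below window_length")
  if (cfg$evaluation$train_frac <= 0 || cfg$evaluation$train_frac >= 1)
    stop2("config: evaluation.train_frac must lie in (0, 1)")
  if (!cfg$selection$mode %in% c("fixed", "dynamic"))
    stop2("config: selection.mode must be 'fixed' or 'dynamic'")
  if (!isTRUE(cfg$generator$enabled) && is.null(cfg$data$path))
    stop2("config: generator disabled and no data.path given")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Test-set predictions of a single holdout repetition
#'
#' Runs one 70/30 split end to end (standardize on train, select components
#' by LOO PRESS, fit, predict, invert) and returns the test-set measured and
#' predicted concentrations — the data behind a measured-vs-predicted
#' scatter plot.
#'
#' @param samples A [sample_table()].
#' @param analyte Analyte name.
#' @param band_set Band indices to use.
#' @param train_frac Training fraction.
#' @param seed Seed of the split (repetition 1 of [repeated_holdout()]'s
#'   sequence under the same seed).
#' @param a_max Cap on the PLS component count.
#' @return data.frame with columns `analyte`, `sample_id`, `experiment`,
#'   `measured`, `predicted`.
#' @export
holdout_predictions <- function(samples, analyte, band_set, train_frac = 0.7,
                                seed = 1, a_max = 15) {
  X <- spectra_matrix(samples)[, band_set, drop = FALSE]
  y <- concentration_matrix(samples)[, analyte]
  n <- nrow(X)
  tr <- make_splits(n, 1, train_frac, seed)[[1]]
  te <- setdiff(seq_len(n), tr)
  std <- standardize_fit_apply(y[tr])
  prof <- select_components(X[tr, , drop = FALSE], std$z, a_max)
  fit <- fit_pls(X[tr, , drop = FALSE], std$z, prof$a_star)
  pred <- standardize_invert(predict_pls(fit, X[te, , drop = FALSE]),
                             std$standardizer)
  data.frame(analyte = analyte, sample_id = samples$sample_id[te],
             experiment = samples$experiment[te],
             measured = y[te], predicted = pred, row.names = NULL)
}

#' Run the full estimation pipeline
#'
#' Executes the end-to-end flow on synthetic or user-supplied data:
#' ingest/generate, (optionally) render per-sample image cubes and recover
#' each mean leaf spectrum through NDVI segmentation, smooth the spectra,
#' compute panel descriptives, evaluate all-band models, partition the
#' wavelength axis by the reflectance CV boundary, evaluate both range
#' models, vote sensitive bands per analyte, evaluate the sensitive-band
#' models, and select the optimal variant per analyte. Every table is
#' written as CSV under `out_dir` together with a JSON manifest recording the
#' configuration and its hash; outputs are byte-identical across runs with
#' the same configuration.
#'
#' @param config A [validate_config()] result, a YAML path, a list, or
#'   `NULL` for defaults.
#' @return Invisibly, a list with the sample table, descriptives, CV
#'   profile, partition, per-variant evaluation tables, frequency tables,
#'   the optimal-model table and the output paths.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  ## --- stage: ingest / generate -------------------------------------------
  if (isTRUE(cfg$generator$enabled)) {
    g <- cfg$generator
    study <- study_config(g$n_exp1, g$n_exp2, g$n_bands, g$wl_min, g$wl_max,
                          cube_shape = g$cube_shape, seed = cfg$seed)
    optics <- optics_config(noise_sd = g$noise_sd,
                            multiplicative_sd = g$multiplicative_sd)
    samples <- generate_study(study, analyte_panel_config(), optics)
    ## optional image round trip: render each sample's cube, segment by
    ## NDVI > 0 and re-extract the mean leaf spectrum
    if (isTRUE(g$use_cubes)) {
      spec <- spectra_matrix(samples)
      wl <- wavelengths(samples)
      for (i in seq_len(nrow(spec))) {
        cb <- generate_cube(spec[i, ], wl, shape = g$cube_shape,
                            seed = child_seed(cfg$seed, SEED_STAGE[["cube"]], i),
                            pixel_noise_sd = g$pixel_noise_sd)
        mask <- segment_leaf(ndvi_map(cb$cube))
        spec[i, ] <- extract_mean_spectrum(cb$cube, mask)
      }
      samples <- sample_table(concentration_matrix(samples), spec, wl,
                              experiment = samples$experiment,
                              sample_id = samples$sample_id)
    }
  } else {
    samples <- read_sample_table(cfg$data$path)
  }

  ## --- stage: smoothing ----------------------------------------------------
  if (isTRUE(cfg$smoothing$enabled)) {
    sm <- savgol_smooth(spectra_matrix(samples),
                        cfg$smoothing$window_length, cfg$smoothing$polyorder)
    samples <- sample_table(concentration_matrix(samples), sm,
                            wavelengths(samples),
                            experiment = samples$experiment,
                            sample_id = samples$sample_id)
  }
  emit(as.data.frame(samples), "sample_table.csv")
  analytes <- cfg$selection$analytes %||% analyte_names(samples)

  ## --- stage: descriptives -------------------------------------------------
  desc <- descriptive_stats(samples)
  emit(desc, "descriptives.csv")

  ## --- stage: CV partition -------------------------------------------------
  prof <- band_cv_profile(spectra_matrix(samples), wavelengths(samples))
  emit(as.data.frame(prof), "cv_profile.csv")
  part <- partition_bands(wavelengths(samples), cfg$selection$boundary_nm)

  ## --- stage: per-variant evaluations -------------------------------------
  ev <- cfg$evaluation
  all_bands <- seq_along(wavelengths(samples))
  fixed_variants <- list(all_bands = all_bands,
                         low_range = part$low_range,
                         high_range = part$high_range)
  eval_tables <- list()
  for (vn in names(fixed_variants)) {
    rows <- lapply(analytes, function(a) {
      h <- repeated_holdout(samples, a, fixed_variants[[vn]], R = ev$R,
                            train_frac = ev$train_frac, seed = cfg$seed,
                            a_max = ev$a_max)
      data.frame(analyte = a, t(h$means),
                 n_bands = length(fixed_variants[[vn]]))
    })
    eval_tables[[vn]] <- do.call(rbind, rows)
    emit(eval_tables[[vn]], paste0("evaluation_", vn, ".csv"))
  }

  ## --- stage: sensitive-band voting + evaluation ---------------------------
  sel <- cfg$selection
  sens_sets <- list()
  sens_rows <- list()
  for (a in analytes) {
    ft <- vote_sensitive_bands(samples, a, part$low_range, R = sel$R,
                               threshold = sel$threshold,
                               train_frac = ev$train_frac, seed = cfg$seed,
                               a_max = sel$a_max, mode = sel$mode)
    write_frequency_table(ft, file.path(out, paste0("frequency_", a, ".csv")))
    bs <- sensitive_bands(ft)
    sens_sets[[a]] <- bs
    sens_rows[[a]] <- if (length(bs) >= 1) {
      h <- repeated_holdout(samples, a, bs, R = ev$R,
                            train_frac = ev$train_frac, seed = cfg$seed,
                            a_max = ev$a_max)
      data.frame(analyte = a, t(h$means), n_bands = length(bs))
    } else {
      data.frame(analyte = a, r2 = NA_real_, rmse = NA_real_, re = NA_real_,
                 rpd = NA_real_, n_bands = length(bs))
    }
  }
  eval_tables$sensitive_bands <- do.call(rbind, sens_rows)
  emit(eval_tables$sensitive_bands, "evaluation_sensitive_bands.csv")

  ## --- stage: optimal model per analyte ------------------------------------
  variant_labels <- c(all_bands = "400-1100 nm", low_range = "low range",
                      high_range = "high range",
                      sensitive_bands = "sensitive bands")
  opt_rows <- lapply(analytes, function(a) {
    cand <- do.call(rbind, lapply(names(eval_tables), function(vn) {
      row <- eval_tables[[vn]][eval_tables[[vn]]$analyte == a, ]
      cbind(variant = vn, row)
    }))
    cand <- cand[!is.na(cand$r2), ]
    ord <- order(-cand$r2, -cand$rpd, cand$n_bands, seq_len(nrow(cand)))
    best <- cand[ord[1], ]
    data.frame(analyte = a, variant = best$variant,
               used_bands = variant_labels[[best$variant]],
               r2 = best$r2, rmse = best$rmse, re = best$re, rpd = best$rpd,
               n_bands = best$n_bands, row.names = NULL)
  })
  optimal <- do.call(rbind, opt_rows)
  emit(optimal, "optimal_models.csv")

  ## --- stage: scatter data (measured vs predicted, winner variant) --------
  scatter <- do.call(rbind, lapply(analytes, function(a) {
    vn <- optimal$variant[optimal$analyte == a]
    bs <- switch(vn, sensitive_bands = sens_sets[[a]], fixed_variants[[vn]])
    holdout_predictions(samples, a, bs, ev$train_frac, cfg$seed, ev$a_max)
  }))
  emit(scatter, "scatter_optimal.csv")

  ## --- manifest ------------------------------------------------------------
  cfg_plain <- unclass(cfg)
  cfg_yaml <- file.path(out, "config_normalized.yaml")
  yaml::write_yaml(cfg_plain, cfg_yaml)
  manifest <- list(seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_yaml)),
                   n_samples = nrow(samples),
                   n_bands = length(wavelengths(samples)),
                   outputs = names(paths))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(samples = samples, descriptives = desc, cv_profile = prof,
                 partition = part, evaluations = eval_tables,
                 sensitive_sets = sens_sets, optimal = optimal,
                 scatter = scatter, paths = paths))
}
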