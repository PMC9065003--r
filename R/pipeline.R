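# End-to-end orchestration: simulate (or read) -> preprocess -> band trends
# -> per-week model training/evaluation -> comparison tables + manifest.
# All randomness flows from one root seed, expanded per stage, so a rerun
# with the same config reproduces every deterministic output byte for byte.

#' Default pipeline configuration
#'
#' @param synth A `synth_config` (used when no input files are given).
#' @param spectra_path,meta_path Optional input files (wide spectral table
#'   + metadata sidecar); when NULL the synthetic generator is used.
#' @param preprocess Config list from [preprocess_config()].
#' @param models Model tags to train per week.
#' @param min_week Weeks below this are excluded from regression (default
#'   2: early weeks are too heterogeneous to regress on).
#' @param test_fraction,cv_folds Evaluation protocol (0.2 / 5).
#' @param loco_left_out Concentration (mM) for the leave-one-group-out
#'   experiment, or NULL to skip.
#' @param band_window Deconvolution window for center trends, cm^-1.
#' @param seed Root seed.
#' @return Named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(synth = synth_config(),
                            spectra_path = NULL, meta_path = NULL,
                            preprocess = preprocess_config(),
                            models = c("gpr-rq", "ridge", "tree"),
                            min_week = 2, test_fraction = 0.2,
                            cv_folds = 5L, loco_left_out = NULL,
                            band_window = c(1590, 1720), seed = 1L) {
  list(synth = synth, spectra_path = spectra_path, meta_path = meta_path,
       preprocess = preprocess, models = models, min_week = min_week,
       test_fraction = test_fraction, cv_folds = cv_folds,
       loco_left_out = loco_left_out, band_window = band_window,
       seed = as.integer(seed))
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("seed")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop_ramansalt("config", "config is missing required field(s): ",
                   paste(miss, collapse = ", "))
  }
  cfg <- pipeline_config(seed = raw$seed)
  if (!is.null(raw$synth)) cfg$synth <- do.call(synth_config, raw$synth)
  for (nm in intersect(names(raw), c("spectra_path", "meta_path", "models",
                                     "min_week", "test_fraction",
                                     "cv_folds", "loco_left_out",
                                     "band_window"))) {
    cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$preprocess)) {
    cfg$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_ramansalt("stage", "stage '", name, "' failed: ",
                   conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data acquisition (synthetic generation or file
#' ingest), preprocessing (boxcar, baseline, L2 norm, quantile
#' elimination), band intensity trends, per-week model training with a
#' stratified 80/20 split and k-fold CV, evaluation, and an optional
#' leave-one-concentration-out experiment. Writes a model-comparison table
#' (RMSE and R^2 per week and model), a per-group spectrum count table,
#' the band-trend table, per-week evaluation JSON, and a run manifest with
#' MD5 digests of every artifact.
#'
#' @param config From [pipeline_config()], or a path to a YAML file
#'   mirroring its fields.
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress to stderr.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "pipeline_out",
                         verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[ramansalt] ", ...)
  t0 <- Sys.time()
  seed <- config$seed

  log_msg("stage: acquire")
  data <- stage("acquire", {
    if (is.null(config$spectra_path)) {
      cfg <- config$synth
      cfg$seed <- seed
      generate_dataset(cfg)$set
    } else {
      s <- read_spectrum_table(config$spectra_path, "wide")
      attach_metadata(s, config$meta_path)
    }
  })

  log_msg("stage: preprocess (", n_spectra(data), " spectra)")
  pp <- stage("preprocess",
              preprocess_pipeline(data, config$preprocess))
  counts <- group_count_table(pp$set)
  counts_path <- file.path(out_dir, "group_counts.csv")
  utils::write.csv(counts, counts_path, row.names = FALSE)

  log_msg("stage: band trends")
  trends <- stage("bands", {
    bands <- reference_bands()[1:5, ]
    bands$half_window <- 8
    band_trends(pp$set, bands, mode = "intensity")
  })
  trends_path <- file.path(out_dir, "band_trends.csv")
  utils::write.csv(trends, trends_path, row.names = FALSE)

  log_msg("stage: train/evaluate")
  weeks <- sort(unique(pp$set$meta$week))
  weeks <- weeks[weeks >= config$min_week]
  comparison <- list()
  eval_files <- character(0)
  for (w in weeks) {
    m <- pp$set$meta$week == w
    X <- pp$set$intensities[m, , drop = FALSE]
    y <- pp$set$meta$concentration_mM[m]
    sp <- split_train_test(y, config$test_fraction, seed = seed + w)
    for (tag in config$models) {
      fit <- stage(paste0("train:", tag, ":week", w),
                   fit_salt_model(X[sp$train, , drop = FALSE], y[sp$train],
                                  tag, seed = seed + w))
      rep <- evaluate(fit, X[sp$test, , drop = FALSE], y[sp$test],
                      model_tag = tag, week = w)
      comparison[[length(comparison) + 1L]] <- data.frame(
        week = w, model = tag, rmse_mM = rep$rmse, r2 = rep$r2,
        n_train = length(sp$train), n_test = length(sp$test))
      ev_path <- file.path(out_dir, sprintf("eval_week%d_%s.json", w, tag))
      jsonlite::write_json(
        list(week = w, model = tag, seed = seed + w, rmse = rep$rmse,
             r2 = rep$r2, residuals = rep$residuals,
             per_concentration_medians =
               as.list(rep$per_concentration_medians),
             hyperparameters = if (inherits(fit, "gpr_model")) fit$params),
        ev_path, auto_unbox = TRUE, digits = NA)
      eval_files <- c(eval_files, ev_path)
      log_msg(sprintf("  week %d %-8s RMSE %6.2f mM  R2 %.4f",
                      w, tag, rep$rmse, rep$r2))
    }
  }
  comparison <- do.call(rbind, comparison)
  comparison_path <- file.path(out_dir, "model_comparison.csv")
  utils::write.csv(comparison, comparison_path, row.names = FALSE)

  loco_path <- NULL
  if (!is.null(config$loco_left_out)) {
    log_msg("stage: leave-one-concentration-out (", config$loco_left_out,
            " mM)")
    w <- weeks[length(weeks) %/% 2 + 1]  # middle regression week
    m <- pp$set$meta$week == w
    loco <- stage("loco", leave_one_concentration_out(
      pp$set$intensities[m, , drop = FALSE],
      pp$set$meta$concentration_mM[m],
      left_out = config$loco_left_out, model = config$models[1],
      seed = seed + 100L))
    loco_path <- file.path(out_dir, "loco.json")
    jsonlite::write_json(
      list(week = w, left_out_mM = config$loco_left_out,
           median_deviation_mM = loco$median_deviation,
           rmse = loco$report$rmse),
      loco_path, auto_unbox = TRUE, digits = NA)
  }

  files <- c(counts_path, trends_path, comparison_path, eval_files,
             loco_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ramansalt")),
    seed = seed,
    config = config[setdiff(names(config), "synth")],
    n_input_spectra = n_spectra(data),
    n_after_filter = n_spectra(pp$set),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(path = f,
                                    md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_msg("done")
  invisible(manifest)
}
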