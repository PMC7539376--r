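#' Assemble a reproducible run configuration
#'
#' A flat, fully serializable description of one experiment: where the
#' manifest lives, which MS level and window spec to use, the model and
#' training settings, the master seed and the output directory. An
#' archived copy is written beside every result set so a run can be
#' reproduced bit for bit.
#'
#' @param manifest Path to the sample manifest CSV.
#' @param ms_level 1 or 2.
#' @param windows Window spec (integer or `"NxN"`).
#' @param mz_min,mz_max Optional explicit grid bounds; inferred from the
#'   pooled runs when `NULL`.
#' @param epochs,batch_size,learning_rate,validation_fraction Training
#'   settings (see [training_config()]).
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory.
#' @return A `RunConfig` list.
#' @export
run_config <- function(manifest, ms_level = 1L, windows = "32x32",
                       mz_min = NULL, mz_max = NULL,
                       epochs = 30L, batch_size = 128L,
                       learning_rate = 1e-3, validation_fraction = 0.1,
                       seed = 1L, out_dir = "specswath_results") {
  structure(list(manifest = manifest, ms_level = as.integer(ms_level),
                 windows = as.character(windows),
                 mz_min = mz_min, mz_max = mz_max,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

#' Save / load a run configuration (YAML)
#'
#' @param config A `RunConfig`.
#' @param path YAML file path.
#' @return `save_run_config`: `path` invisibly; `load_run_config`: the
#'   reconstructed `RunConfig`.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Window-size sweep
#'
#' Reruns the full leave-one-out protocol once per window spec with the
#' same master seed, tabulating cohort accuracy against feature
#' resolution. Coarse grids merge class-signature loci into shared bins
#' and are expected to lose accuracy. A failing spec is reported in its
#' row's `error` column; the sweep continues with the remaining specs.
#'
#' @param runs List of labelled `SpectraRun`.
#' @param size_specs Character/integer vector of window specs (>= 1).
#' @param spec Optional `ModelSpec` (default: sized per grid).
#' @param config `TrainingConfig` carrying the master seed.
#' @param mz_range Optional shared `c(min, max)`; inferred when `NULL`.
#' @return data.frame with columns `size_spec`, `n_windows`,
#'   `loo_accuracy`, `error`.
#' @export
sweep_window_sizes <- function(runs, size_specs, spec = NULL,
                               config = training_config(),
                               mz_range = NULL) {
  stopifnot(length(size_specs) >= 1L)
  if (is.null(mz_range)) mz_range <- infer_mz_range(runs)
  rows <- lapply(size_specs, function(ss) {
    tryCatch({
      grid <- build_window_grid(mz_range[1], mz_range[2], ss)
      res <- run_loo(runs, grid, spec, config)
      data.frame(size_spec = as.character(ss), n_windows = grid$n_windows,
                 loo_accuracy = res$accuracy, error = NA_character_)
    }, error = function(e)
      data.frame(size_spec = as.character(ss), n_windows = NA_integer_,
                 loo_accuracy = NA_real_,
                 error = conditionMessage(e)))
  })
  do.call(rbind, rows)
}

#' End-to-end pipeline: manifest to metrics
#'
#' Reads every run of the manifest at the configured MS level, builds the
#' shared window grid, executes the leave-one-out cross prediction, and
#' writes all artifacts into the output directory: the normalized feature
#' matrix, the per-sample prediction table, metrics as JSON and CSV, ROC
#' points, a log of per-stage counters and an archived copy of the config.
#' Rerunning with the same config reproduces every CSV bit for bit.
#'
#' @param config A `RunConfig`.
#' @return The output directory, invisibly; metrics are also returned as
#'   the attribute `"metrics"`.
#' @export
end_to_end <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!file.exists(config$manifest))
    stop("manifest not found: ", config$manifest)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, msg)
  }
  manifest <- load_manifest(config$manifest)
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- suppressMessages(
      read_spectra(manifest$file[i], ms_level = config$ms_level,
                   sample_label = manifest$label[i]))
    note("read %s: %d scans at MS%d", r$run_id, n_scans(r), config$ms_level)
    r
  })
  rng <- if (!is.null(config$mz_min) && !is.null(config$mz_max))
    c(config$mz_min, config$mz_max) else infer_mz_range(runs)
  grid <- build_window_grid(rng[1], rng[2], config$windows)
  note("grid: %d windows of %.4f Th over [%.1f, %.1f]",
       grid$n_windows, grid$window_width, grid$mz_min, grid$mz_max)
  tc <- training_config(epochs = config$epochs,
                        batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        seed = config$seed,
                        validation_fraction = config$validation_fraction)
  pooled <- suppressMessages(pool_features(runs, grid))
  write_matrix_csv(pooled$features,
                   file.path(config$out_dir, "normalized_matrix.csv"))
  res <- suppressMessages(run_loo(runs, grid, spec = NULL, config = tc))
  note("leave-one-out: %d/%d samples correct", res$n_predicted, res$n_total)
  rpt <- suppressWarnings(metrics_report(res))
  data.table::fwrite(sample_prediction_table(res),
                     file.path(config$out_dir, "sample_predictions.csv"))
  metr <- list(accuracy = rpt$accuracy, precision = rpt$precision,
               recall = rpt$recall, f1 = rpt$f1, auc = rpt$auc,
               n_total = res$n_total, n_predicted = res$n_predicted)
  jsonlite::write_json(metr, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(as.data.frame(metr),
                     file.path(config$out_dir, "metrics.csv"))
  if (!is.null(rpt$roc_points))
    data.table::fwrite(rpt$roc_points,
                       file.path(config$out_dir, "roc_points.csv"))
  if (!is.null(rpt$per_class))
    data.table::fwrite(rpt$per_class,
                       file.path(config$out_dir, "per_class_metrics.csv"))
  save_run_config(config, file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, logf)
  out <- config$out_dir
  attr(out, "metrics") <- rpt
  invisible(out)
}
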