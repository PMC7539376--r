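#' Leave-one-out split of a cohort
#'
#' Yields one iteration per run: that run is the independent test set and
#' every other run is training data. No scan of the held-out run ever
#' reaches the training pool.
#'
#' @param runs List of labelled `SpectraRun` (>= 2 runs, >= 2 classes
#'   overall).
#' @return List of iterations, each a list with `test_index`, `test_run`
#'   and `train_runs`.
#' @export
loo_split <- function(runs) {
  if (length(runs) < 2L) stop("leave-one-out needs at least 2 runs")
  labels <- vapply(runs, `[[`, integer(1), "sample_label")
  if (anyNA(labels)) stop("all runs must carry a sample label")
  if (length(unique(labels)) < 2L)
    stop("cohort contains a single class; need at least two")
  lapply(seq_along(runs), function(k)
    list(test_index = k, test_run = runs[[k]], train_runs = runs[-k]))
}

#' Majority-vote verdict for one held-out sample
#'
#' Binary mode implements the scan-vote rule: the fraction of scans whose
#' predicted label equals the sample's original label is the correct ratio,
#' and the sample is predicted correctly when that ratio is >= 0.5 (the
#' boundary counts as correct). Multiclass mode instead averages the
#' per-scan class probabilities and predicts the argmax class.
#'
#' @param per_scan_labels Integer vector of predicted labels, one per scan.
#' @param original_label The run's true label.
#' @param per_scan_probs Matrix of per-scan class probabilities (columns
#'   named by class); required for multiclass, optional for binary.
#' @param mode `"binary"` or `"multiclass"`.
#' @param run_id Identifier carried into the result.
#' @return A `SamplePrediction` with fields `run_id`, `original_label`,
#'   `per_scan_labels`, `per_scan_probs`, `correct_ratio`, `mean_probs`,
#'   `predicted_label` and `verdict` (`"correct"` or `"wrong"`).
#' @export
evaluate_sample <- function(per_scan_labels, original_label,
                            per_scan_probs = NULL,
                            mode = c("binary", "multiclass"),
                            run_id = NA_character_) {
  mode <- match.arg(mode)
  if (length(per_scan_labels) == 0L)
    stop("cannot evaluate a sample with zero scans")
  original_label <- as.integer(original_label)
  per_scan_labels <- as.integer(per_scan_labels)
  correct_ratio <- mean(per_scan_labels == original_label)
  mean_probs <- if (!is.null(per_scan_probs)) colMeans(per_scan_probs) else NULL
  if (mode == "binary") {
    correct <- correct_ratio >= 0.5
    # In a 2-class task the >= 0.5 vote rule pins the predicted label:
    # the majority label is the original one iff the sample is correct.
    others <- setdiff(unique(per_scan_labels), original_label)
    predicted <- if (correct) original_label
                 else if (length(others)) others[1L] else original_label
  } else {
    if (is.null(mean_probs))
      stop("multiclass verdicts need per_scan_probs")
    predicted <- as.integer(names(mean_probs)[which.max(mean_probs)])
    correct <- predicted == original_label
  }
  structure(
    list(run_id = run_id, original_label = original_label,
         per_scan_labels = per_scan_labels, per_scan_probs = per_scan_probs,
         correct_ratio = correct_ratio, mean_probs = mean_probs,
         predicted_label = as.integer(predicted),
         verdict = if (correct) "correct" else "wrong"),
    class = "SamplePrediction"
  )
}

#' @export
print.SamplePrediction <- function(x, ...) {
  cat(sprintf("SamplePrediction '%s': original %d, predicted %d, ratio %.3f -> %s\n",
              x$run_id, x$original_label, x$predicted_label,
              x$correct_ratio, x$verdict))
  invisible(x)
}

#' Run the full leave-one-out cross prediction
#'
#' Features are extracted once per run on the shared grid and row-normalized
#' (both are per-scan operations, so precomputation cannot leak information
#' across the split). Each iteration trains a fresh model on the pooled
#' training rows with a per-iteration seed derived from the master seed
#' (`config$seed + iteration`), predicts every scan of the held-out run,
#' and records the sample verdict. Scan-level (true label, positive-class
#' probability) pairs are pooled across iterations for ROC analysis.
#'
#' @param runs List of labelled `SpectraRun` sharing one MS level.
#' @param grid Shared `WindowGrid`; defaults to a 32x32 (1024-window) grid
#'   over the cohort's inferred m/z range.
#' @param spec `ModelSpec`; defaults to [default_model_spec()] for the grid
#'   size and class count.
#' @param config `TrainingConfig`; its `seed` is the master seed.
#' @param predictor Optional function `(train_x, train_labels, test_x,
#'   seed)` returning a list with `labels` and `probs`, replacing the
#'   train+predict stage. Used to inject reference predictors in tests.
#' @return A `CohortResult` with `predictions` (list of
#'   `SamplePrediction`), `n_total`, `n_predicted`, `accuracy` (their
#'   ratio), `pooled_scan_scores` (data.frame `label`, `prob` — binary
#'   cohorts only) and `mode`.
#' @export
run_loo <- function(runs, grid = NULL, spec = NULL,
                    config = training_config(), predictor = NULL) {
  splits <- loo_split(runs)
  if (is.null(grid))
    grid <- build_window_grid(infer_mz_range(runs)[1], infer_mz_range(runs)[2],
                              "32x32")
  labels <- vapply(runs, `[[`, integer(1), "sample_label")
  classes <- sort(unique(labels))
  mode <- if (length(classes) == 2L) "binary" else "multiclass"
  per_run <- lapply(runs, function(r)
    normalize_rows(extract_feature_swath(r, grid))$values)

  preds <- vector("list", length(runs))
  pooled <- vector("list", length(runs))
  for (it in splits) {
    k <- it$test_index
    tr_labels <- unlist(lapply(it$train_runs, make_label_vector),
                        use.names = FALSE)
    if (length(unique(tr_labels)) < 2L)
      stop("iteration ", k, " (test run '", it$test_run$run_id,
           "'): training set is single-class")
    tr_x <- do.call(rbind, per_run[-k])
    te_x <- per_run[[k]]
    seed_k <- config$seed + k
    res <- tryCatch({
      if (!is.null(predictor)) {
        predictor(tr_x, tr_labels, te_x, seed_k)
      } else {
        cfg_k <- config; cfg_k$seed <- seed_k
        spec_k <- if (is.null(spec))
          default_model_spec(grid$n_windows, length(classes)) else spec
        mdl <- train_model(tr_x, tr_labels, spec_k, cfg_k)
        predict_scans(mdl, te_x)
      }
    }, error = function(e)
      stop("iteration ", k, " (test run '", it$test_run$run_id, "'): ",
           conditionMessage(e), call. = FALSE))
    preds[[k]] <- evaluate_sample(res$labels, it$test_run$sample_label,
                                  per_scan_probs = res$probs, mode = mode,
                                  run_id = it$test_run$run_id)
    if (mode == "binary") {
      pos <- as.character(classes[2L])
      p <- if (!is.null(res$probs) && pos %in% colnames(res$probs))
        res$probs[, pos] else as.numeric(res$labels == classes[2L])
      pooled[[k]] <- data.frame(label = rep(it$test_run$sample_label,
                                            length(res$labels)),
                                prob = as.numeric(p))
    }
  }
  n_pred <- sum(vapply(preds, function(p) p$verdict == "correct", logical(1)))
  structure(
    list(predictions = preds, n_total = length(runs), n_predicted = n_pred,
         accuracy = n_pred / length(runs),
         pooled_scan_scores = if (mode == "binary")
           do.call(rbind, pooled) else NULL,
         mode = mode, classes = classes, grid = grid, seed = config$seed),
    class = "CohortResult"
  )
}

#' @export
print.CohortResult <- function(x, ...) {
  cat(sprintf("CohortResult (%s): %d/%d samples predicted correctly, accuracy %.3f\n",
              x$mode, x$n_predicted, x$n_total, x$accuracy))
  for (p in x$predictions)
    cat(sprintf("  %-14s label %d -> %d  ratio %.3f  %s\n", p$run_id,
                p$original_label, p$predicted_label, p$correct_ratio,
                p$verdict))
  invisible(x)
}

#' Per-sample prediction table
#'
#' @param result A `CohortResult`.
#' @return data.frame with one row per sample: run id, original and
#'   predicted labels, scan-vote correct ratio, per-class mean
#'   probabilities and the verdict.
#' @export
sample_prediction_table <- function(result) {
  stopifnot(inherits(result, "CohortResult"))
  rows <- lapply(result$predictions, function(p) {
    df <- data.frame(run_id = p$run_id, original_label = p$original_label,
                     predicted_label = p$predicted_label,
                     correct_ratio = p$correct_ratio, verdict = p$verdict)
    if (!is.null(p$mean_probs)) {
      mp <- as.data.frame(as.list(p$mean_probs), check.names = FALSE)
      names(mp) <- paste0("mean_prob_", names(p$mean_probs))
      df <- cbind(df, mp)
    }
    df
  })
  do.call(rbind, rows)
}
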