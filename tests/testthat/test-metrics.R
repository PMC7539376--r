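verdicts <- function(pairs) {
  data.frame(original_label = vapply(pairs, `[[`, numeric(1), 1),
             predicted_label = vapply(pairs, `[[`, numeric(1), 2))
}

test_that("confusion counts tally verdicts against the chosen positive class", {
  df <- verdicts(list(c(1, 1), c(1, 1), c(1, 0), c(0, 1)))
  cc <- confusion_counts(df, positive_class = 1)
  expect_equal(cc$TP, 2L); expect_equal(cc$FP, 1L)
  expect_equal(cc$FN, 1L); expect_equal(cc$TN, 0L)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, nrow(df))

  all_right <- verdicts(list(c(1, 1), c(0, 0), c(1, 1)))
  cc2 <- confusion_counts(all_right, 1)
  expect_equal(cc2$FP, 0L); expect_equal(cc2$FN, 0L)

  # flipping the positive class swaps (TP,TN) and (FP,FN)
  flip <- confusion_counts(df, positive_class = 0)
  expect_equal(flip$TP, cc$TN); expect_equal(flip$TN, cc$TP)
  expect_equal(flip$FP, cc$FN); expect_equal(flip$FN, cc$FP)

  tri <- verdicts(list(c(0, 0), c(1, 1), c(2, 2)))
  expect_error(confusion_counts(tri), "multiclass")
})

test_that("F1 reproduces published worked examples at three decimals", {
  expect_equal(round(f1_score(0.833, 1.00), 3), 0.909)
  expect_equal(round(f1_score(0.654, 0.811), 3), 0.724)
  expect_equal(round(f1_score(0.696, 0.727), 3), 0.711)
})

test_that("precision/recall/F1 follow their defining ratios, 0 when undefined", {
  cc <- structure(list(TP = 5L, FP = 1L, FN = 0L, TN = 4L,
                       positive_class = 1L), class = "ConfusionCounts")
  prf <- precision_recall_f1(cc)
  expect_equal(prf$precision, 5 / 6)
  expect_equal(prf$recall, 1)
  expect_equal(prf$f1, 2 * (5 / 6) / (5 / 6 + 1))

  zero <- structure(list(TP = 0L, FP = 0L, FN = 5L, TN = 0L,
                         positive_class = 1L), class = "ConfusionCounts")
  expect_warning(z <- precision_recall_f1(zero), "undefined")
  expect_equal(unlist(z), c(precision = 0, recall = 0, f1 = 0))
})

test_that("cohort accuracy is the correct-verdict fraction", {
  fake <- structure(list(n_total = 10L, n_predicted = 9L),
                    class = "CohortResult")
  expect_equal(cohort_accuracy(fake), 0.9)
  expect_equal(cohort_accuracy(structure(list(n_total = 4L, n_predicted = 0L),
                                         class = "CohortResult")), 0)
  expect_error(cohort_accuracy(structure(list(n_total = 0L, n_predicted = 0L),
                                         class = "CohortResult")), "empty")
})

test_that("ROC endpoints and degenerate score sets behave canonically", {
  perfect <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auc, 1.0)
  flat <- roc_auc(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$roc_points$fpr, c(0, 1))
  expect_equal(flat$roc_points$tpr, c(0, 1))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("threshold-sweep AUC equals the concordant-pair probability", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 30
    labels <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    # coarse scores force ties across and within classes
    scores <- round(runif(n), 1)
    r <- roc_auc(labels, scores)
    expect_equal(r$auc, pair_auc(labels, scores), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  set.seed(13)
  labels <- sample(0:1, 40, replace = TRUE); labels[1:2] <- 0:1
  scores <- runif(40)
  r <- roc_auc(labels, scores)
  expect_equal(r$roc_points$fpr[1], 0)
  expect_equal(r$roc_points$tpr[1], 0)
  expect_equal(tail(r$roc_points$fpr, 1), 1)
  expect_equal(tail(r$roc_points$tpr, 1), 1)
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
})

test_that("AUC is rank-based: monotone transforms keep it, negation flips it", {
  set.seed(99)
  labels <- sample(0:1, 25, replace = TRUE); labels[1:2] <- 0:1
  scores <- runif(25)  # continuous, so tie-free almost surely
  base <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, exp(3 * scores))$auc, base)
  expect_equal(roc_auc(labels, rank(scores))$auc, base)
  expect_equal(roc_auc(labels, -scores)$auc, 1 - base)
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  labels <- sample(0:1, 60, replace = TRUE); labels[1:2] <- 0:1
  scores <- round(runif(60), 2)
  ours <- roc_auc(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("reported F1 always re-derives from reported precision and recall", {
  set.seed(42)
  runs <- generate_cohort(small_cohort_config(seed = 42, scans = 10))
  grid <- build_window_grid(infer_mz_range(runs)[1], infer_mz_range(runs)[2],
                            "6x6")
  noisy <- function(train_x, train_labels, test_x, seed) {
    set.seed(seed)
    lab <- sample(0:1, nrow(test_x), replace = TRUE)
    list(labels = lab, probs = cbind(`0` = 1 - lab, `1` = lab))
  }
  res <- run_loo(runs, grid, config = fast_training(seed = 8),
                 predictor = noisy)
  rpt <- suppressWarnings(metrics_report(res))
  if (rpt$precision + rpt$recall > 0)
    expect_equal(rpt$f1,
                 2 * rpt$precision * rpt$recall / (rpt$precision + rpt$recall),
                 tolerance = 1e-12)
  expect_true(rpt$f1 >= 0 && rpt$f1 <= 1)
})

test_that("multiclass reports give one-vs-rest rows plus macro averages", {
  df <- verdicts(list(c(0, 0), c(0, 1), c(1, 1), c(1, 1), c(2, 2), c(2, 0)))
  fake <- structure(list(predictions = NULL, n_total = 6L, n_predicted = 4L,
                         accuracy = 4 / 6, mode = "multiclass"),
                    class = "CohortResult")
  per <- suppressWarnings(multiclass_metrics(df))
  expect_equal(nrow(per), 3L)
  expect_equal(per$class, c(0, 1, 2))
  # class 1: TP=2 (both predicted 1 correctly... one 0 predicted as 1 -> FP)
  expect_equal(per$recall[per$class == 1], 1)
  expect_equal(per$precision[per$class == 1], 2 / 3)
})
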