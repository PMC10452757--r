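test_that("MAIS is the maximum regional code and binarizes at 3", {
  expect_equal(mais(2, 3), 3L)
  expect_equal(mais(1, 1), 1L)
  expect_equal(mais(5, 2), 5L)
  expect_equal(mais(ais_band(c(2, 5)), ais_band(c(3, 2))), c(3L, 5L))
  expect_true(binarize_serious(3))
  expect_false(binarize_serious(2))
  expect_true(binarize_serious(5))
  expect_error(binarize_serious(0), "1..5")
  expect_error(binarize_serious(6), "1..5")
})

test_that("confusion matrix counts lay out as TP/FN/FP/TN", {
  got <- confusion_matrix(
    predicted = c(TRUE, TRUE, FALSE, FALSE),
    observed = c(TRUE, FALSE, TRUE, FALSE)
  )
  expect_equal(got, c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  allc <- confusion_matrix(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(allc[["FN"]], 0L)
  expect_equal(allc[["FP"]], 0L)
  expect_error(confusion_matrix(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("confusion and consistency counts match direct tally oracles", {
  set.seed(31)
  pred_f <- runif(1000) < 0.4
  obs_f <- runif(1000) < 0.3
  got <- confusion_matrix(pred_f, obs_f)
  tally <- c(TP = 0L, FN = 0L, FP = 0L, TN = 0L)
  for (i in 1:1000) {
    cell <- if (pred_f[i] && obs_f[i]) "TP" else if (!pred_f[i] && obs_f[i]) {
      "FN"
    } else if (pred_f[i]) "FP" else "TN"
    tally[cell] <- tally[cell] + 1L
  }
  expect_equal(got, tally)
  expect_equal(sum(got), 1000L)

  pm <- sample(1:5, 500, replace = TRUE)
  om <- sample(1:5, 500, replace = TRUE)
  cc <- consistency_counts(pm, om)
  ct <- c(equal = 0L, over = 0L, under = 0L)
  for (i in 1:500) {
    k <- if (pm[i] == om[i]) "equal" else if (pm[i] > om[i]) "over" else "under"
    ct[k] <- ct[k] + 1L
  }
  expect_equal(cc, ct)
  expect_equal(sum(cc), 500L)
  expect_equal(consistency_counts(c(3, 2, 4), c(3, 3, 2)),
               c(equal = 1L, over = 1L, under = 1L))
  expect_equal(consistency_counts(1:5, 1:5)[["equal"]], 5L)
})

test_that("ROC handles the canonical hand-worked cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "undefined")
})

test_that("the ROC curve is a staircase from (0,0) to (1,1)", {
  set.seed(8)
  r <- roc_auc(runif(50), runif(50) < 0.5)
  pts <- r$roc_points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("trapezoid AUC equals the Mann-Whitney statistic with ties", {
  set.seed(104)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    # discretized scores force ties
    scores <- round(runif(n), sample(1:2, 1))
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- round(runif(80), 2)
  labels <- runif(80) < 0.4
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, quiet = TRUE,
    direction = "<", levels = c(FALSE, TRUE)
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC values grade into the published accuracy bands", {
  expect_equal(accuracy_grade(0.747), "medium")
  expect_equal(accuracy_grade(0.95), "high")
  expect_equal(accuracy_grade(0.65), "low")
  expect_equal(accuracy_grade(0.3), "below-chance")
  expect_equal(accuracy_grade(0.9), "medium")
  expect_error(accuracy_grade(1.2), "\\[0, 1\\]")
})
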