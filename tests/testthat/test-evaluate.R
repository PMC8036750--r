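test_that("confusion matrix orientation and edge cases", {
  cm <- confusionMatrix2x2(c("b", "b", "m", "m"), c("b", "m", "m", "m"),
                           positive = "m")
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2), ignore_attr = TRUE)
  expect_identical(rownames(cm), c("b", "m"))
  # perfect predictions: diagonal equals class counts
  tr <- rep(c("b", "m"), c(3, 5))
  cmP <- confusionMatrix2x2(tr, tr, "m")
  expect_equal(unname(cmP), matrix(c(3L, 0L, 0L, 5L), 2), ignore_attr = TRUE)
  # all-positive predictor: FN = TN = 0
  cmA <- confusionMatrix2x2(tr, rep("m", 8), "m")
  expect_equal(cmA[1, 1] + cmA[2, 1], 0L)
  expect_error(confusionMatrix2x2(c("a", "b"), c("a"), "b"), "length")
  expect_error(confusionMatrix2x2(c("a", "b", "c"), c("a", "b", "c"), "c"),
               "2 classes")
})

test_that("metrics reproduce the standard formulas with NA on 0/0", {
  cm <- matrix(c(50L, 0L, 0L, 30L), 2)
  expect_equal(unname(classificationMetrics(cm)), rep(100, 4))
  m <- classificationMetrics(matrix(c(40L, 10L, 20L, 30L), 2))
  expect_equal(unname(m["accuracy"]), 100 * 70 / 100)
  expect_equal(unname(m["precision"]), 100 * 30 / 50)
  expect_equal(unname(m["recall"]), 100 * 30 / 40)
  expect_equal(unname(m["f1"]), 2 * 60 * 75 / (60 + 75))
  # no positive predictions -> precision NA with a warning, never 0
  expect_warning(m0 <- classificationMetrics(matrix(c(5L, 2L, 0L, 0L), 2)),
                 "precision")
  expect_true(is.na(m0["precision"]))
  expect_true(is.na(m0["f1"]))
})

test_that("one-decimal reporting rounds half-up", {
  expect_equal(reportMetrics(c(87.9375, 98.625, 95.55)),
               c(87.9, 98.6, 95.6))
  expect_equal(reportMetrics(87.25), 87.3)  # half-up, not banker's
})

test_that("ROC/AUC agrees with the pairwise estimator and pROC", {
  r <- rocAuc(c("n", "n", "p", "p"), c(0.1, 0.4, 0.35, 0.8), "p")
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("a", "b")
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    auc <- rocAuc(truth, sc, "b")$auc
    expect_equal(auc, bruteAUC(truth, sc, "b"), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(18)
    truth <- sample(c("n", "p"), 60, replace = TRUE)
    sc <- runif(60) + (truth == "p")
    expect_equal(rocAuc(truth, sc, "p")$auc,
                 as.numeric(suppressMessages(
                   pROC::auc(truth == "p", sc))),
                 tolerance = 1e-12)
  }
})

test_that("AUC is monotone-invariant and flips under label inversion", {
  set.seed(19)
  truth <- rep(c("n", "p"), each = 25)
  sc <- runif(50) + (truth == "p") * 0.4
  a1 <- rocAuc(truth, sc, "p")$auc
  expect_equal(rocAuc(truth, exp(3 * sc), "p")$auc, a1, tolerance = 1e-12)
  expect_equal(rocAuc(truth, sc, "n")$auc, 1 - a1, tolerance = 1e-12)
  # perfect separation
  expect_equal(rocAuc(truth, as.numeric(truth == "p"), "p")$auc, 1.0)
  expect_error(rocAuc(rep("p", 5), runif(5), "p"), "both classes")
})

test_that("hypothesis thresholds are inclusive and task-specific", {
  res <- checkHypothesis(c(internal_bm = 98.9, internal_grade = 91.2,
                           external_bm = 94.1))
  expect_true(all(res$pass))
  expect_equal(res$threshold, c(90, 80, 85))
  expect_true(checkHypothesis(c(internal_bm = 90.0),
                              tasks = "internal_bm")$pass)
  expect_false(checkHypothesis(c(internal_grade = 79.9),
                               tasks = "internal_grade")$pass)
  expect_error(checkHypothesis(c(internal_bm = 95)),
               "missing recall")
  expect_error(checkHypothesis(c(bogus = 1), tasks = "bogus"), "unknown")
})
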