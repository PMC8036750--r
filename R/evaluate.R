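#' 2x2 confusion matrix (rows = actual, columns = predicted)
#'
#' @param truth,pred equal-length label vectors over exactly two classes.
#' @param positive the positive class (malignant / grade 5); the other
#'   observed label is the negative class. Rows and columns are ordered
#'   negative then positive, matching the reported confusion tables.
#' @return 2x2 integer matrix with an attribute \code{positive}.
#' @examples
#' confusionMatrix2x2(c("b", "b", "m", "m"), c("b", "m", "m", "m"), "m")
#' @export
confusionMatrix2x2 <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("truth and pred differ in length", call. = FALSE)
  classes <- sort(unique(c(truth, pred)))
  if (length(classes) > 2L)
    stop("more than 2 classes present", call. = FALSE)
  if (!(positive %in% classes)) classes <- c(classes, positive)
  neg <- setdiff(classes, positive)
  if (length(neg) == 0L) neg <- "negative"
  lev <- c(neg[1], positive)
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  out <- matrix(as.integer(cm), 2, 2, dimnames = dimnames(cm))
  attr(out, "positive") <- positive
  out
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Positive-class metrics in percent: accuracy = 100 (TP + TN) / total,
#' precision = 100 TP / (TP + FP), recall = 100 TP / (TP + FN), F1 = the
#' harmonic mean of precision and recall. Undefined denominators yield
#' \code{NA} with a warning, never a silent 0. Values are returned at full
#' precision; round to one decimal only for reporting (see
#' [reportMetrics()]).
#'
#' @param cm a 2x2 matrix from [confusionMatrix2x2()] (rows actual,
#'   columns predicted, negative class first).
#' @return named numeric vector: accuracy, precision, recall, f1 (percent).
#' @examples
#' cm <- matrix(c(764L, 28L, 36L, 772L), 2)  # rows actual, cols predicted
#' classificationMetrics(cm)["accuracy"]     # 96.0
#' @export
classificationMetrics <- function(cm) {
  stopifnot(identical(dim(cm), c(2L, 2L)))
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  total <- tn + fp + fn + tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  acc <- 100 * (tp + tn) / total
  prec <- if (tp + fp == 0) {
    warning("precision undefined: no positive predictions"); NA_real_
  } else 100 * tp / (tp + fp)
  rec <- if (tp + fn == 0) {
    warning("recall undefined: no positive truths"); NA_real_
  } else 100 * tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' One-decimal report rounding (half-up)
#'
#' @param metrics numeric vector of percentages.
#' @return the vector rounded half-up to one decimal.
#' @export
reportMetrics <- function(metrics) {
  floor(metrics * 10 + 0.5) / 10
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps all unique score thresholds, producing (FPR, TPR) points from
#' (0,0) to (1,1); tied scores cross their threshold simultaneously. The
#' trapezoidal area equals the pairwise-comparison probability estimator
#' (ties counted 1/2) and is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param truth labels; \code{positive} marks the positive class.
#' @param scores numeric positive-class scores.
#' @param positive positive class label.
#' @return list with \code{points} (data.frame fpr, tpr, ordered) and
#'   \code{auc}.
#' @examples
#' rocAuc(c("n", "n", "p", "p"), c(0.1, 0.4, 0.35, 0.8), "p")$auc  # 0.75
#' @export
rocAuc <- function(truth, scores, positive) {
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  y <- as.character(truth) == positive
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # collapse tied scores
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Check task recalls against the study's hypothesis thresholds
#'
#' Pass/fail per evaluation task: internal benign vs. malignant requires
#' recall >= 90, internal grade 3 vs. grade 5 requires >= 80, and the
#' external benign vs. malignant test requires >= 85 (all inclusive).
#'
#' @param recalls named numeric vector or list with entries (percent) for
#'   any of \code{internal_bm}, \code{internal_grade},
#'   \code{external_bm}; all three are required unless \code{tasks} names
#'   a subset.
#' @param tasks which tasks to check (default: all names in
#'   \code{recalls}).
#' @return data.frame: task, recall, threshold, pass.
#' @export
checkHypothesis <- function(recalls,
                            tasks = c("internal_bm", "internal_grade",
                                      "external_bm")) {
  thr <- c(internal_bm = 90, internal_grade = 80, external_bm = 85)
  recalls <- unlist(recalls)
  unknown <- setdiff(tasks, names(thr))
  if (length(unknown))
    stop("unknown task(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missingTasks <- setdiff(tasks, names(recalls))
  if (length(missingTasks))
    stop("missing recall for task(s): ",
         paste(missingTasks, collapse = ", "), call. = FALSE)
  data.frame(task = tasks,
             recall = as.numeric(recalls[tasks]),
             threshold = as.numeric(thr[tasks]),
             pass = as.numeric(recalls[tasks]) >= as.numeric(thr[tasks]),
             stringsAsFactors = FALSE)
}

#' Comparative metrics table across fitted models
#'
#' Scores every model on the same test samples and assembles the
#' comparative layout (one row per model: accuracy, precision, recall, F1
#' at one decimal, plus AUC), together with each model's confusion matrix.
#'
#' @param models named list of \linkS4class{TrainedModel}s.
#' @param newdata test inputs: matrix for classical kinds and/or
#'   \code{list(h =, e =)} for \code{dc_bilstm} (both may be supplied via a
#'   list with elements \code{features} and \code{sequences}).
#' @param truth test labels.
#' @return list with \code{table} (data.frame) and \code{confusions}
#'   (named list of 2x2 matrices).
#' @export
comparativeReport <- function(models, newdata, truth) {
  rows <- list(); cms <- list()
  for (nm in names(models)) {
    mdl <- models[[nm]]
    nd <- if (mdl@kind == "dc_bilstm") {
      if (!is.null(newdata$sequences)) newdata$sequences else newdata
    } else {
      if (!is.null(newdata$features)) newdata$features else newdata
    }
    pr <- predictScores(mdl, nd)
    cm <- confusionMatrix2x2(truth, pr$label, mdl@positiveClass)
    met <- reportMetrics(classificationMetrics(cm))
    auc <- rocAuc(truth, pr$score, mdl@positiveClass)$auc
    rows[[nm]] <- data.frame(model = nm, t(met), auc = round(auc, 3))
    cms[[nm]] <- cm
  }
  list(table = do.call(rbind, rows), confusions = cms)
}
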