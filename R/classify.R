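#' Train a classical binary tissue classifier
#'
#' One interface over the four classical model kinds so the comparative
#' analysis is a single loop: RBF-kernel SVM (\pkg{e1071}, cost 1,
#' probability outputs), L2 logistic regression (\code{stats::glm}), a
#' bagging tree (\pkg{randomForest} with \code{mtry = p}, i.e. bagged
#' unpruned trees) and a gradient boosting tree (\pkg{xgboost}; 100 trees,
#' depth 3, learning rate 0.1). The positive class is fixed by convention:
#' malignant, or grade5, otherwise the alphabetically last label.
#'
#' @param x samples-by-features numeric matrix with column names (the kept,
#'   standardized dual-channel features, both channels concatenated).
#' @param labels binary class labels.
#' @param kind one of "svm", "lr", "bagging", "boosting".
#' @param config named list of hyperparameter overrides (\code{cost},
#'   \code{ntree}, \code{nrounds}, \code{max_depth}, \code{eta}).
#' @param seed integer seed; training is deterministic given (data, config,
#'   seed).
#' @return a \linkS4class{TrainedModel}.
#' @export
trainClassifier <- function(x, labels, kind = c("svm", "lr", "bagging",
                                                "boosting"),
                            config = list(), seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  pos <- positiveLabel(lv)
  config$negativeClass <- setdiff(lv, pos)[1]
  y <- factor(labels, levels = c(setdiff(lv, pos), pos))
  set.seed(seed)
  fit <- switch(kind,
    svm = e1071::svm(x, y, kernel = "radial",
                     cost = config$cost %||% 1,
                     probability = TRUE, scale = FALSE),
    lr = {
      df <- data.frame(.y = as.numeric(y == pos), x, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    bagging = randomForest::randomForest(
      x, y, ntree = config$ntree %||% 100L, mtry = ncol(x)),
    boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = config$max_depth %||% 3L,
                    eta = config$eta %||% 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y == pos)),
      nrounds = config$nrounds %||% 100L, verbose = 0))
  new("TrainedModel", kind = kind, fit = fit, featureNames = colnames(x),
      positiveClass = pos, config = config, seed = as.integer(seed))
}

#' Train the dual-channel bidirectional LSTM
#'
#' Two input channels (Hematoxylin and Eosin), each processed by two
#' stacked bidirectional LSTM layers of \code{hidden} cells; each layer
#' concatenates its forward and backward passes, the terminal states of the
#' second layer of both channels are concatenated into a single feature
#' vector and passed to a fully connected 2-way softmax layer. Trained with
#' cross-entropy and Adam, with early stopping on validation loss (best
#' weights restored).
#'
#' Two input modes are supported. \code{"feature"} (default): each
#' channel's k selected FOS features form a sequence of length k, one
#' scalar per time step, ordered by decreasing RFE rank. \code{"patch_rows"}:
#' each 64x64 channel patch is fed as 64 time steps of 64 values.
#'
#' @param hX,eX per-channel inputs: samples x k matrices (feature mode) or
#'   samples x 64 x 64 arrays (patch-rows mode), row-aligned.
#' @param labels binary class labels aligned with the rows.
#' @param valH,valE,valLabels optional validation inputs for early
#'   stopping; when omitted the training loss is monitored.
#' @param config list: \code{hidden} (default 64), \code{epochs} (100),
#'   \code{batch} (64), \code{lr} (1e-3), \code{patience} (10).
#' @param seed integer seed (weight init and batch shuffling).
#' @param verbose print per-epoch losses.
#' @return a \linkS4class{TrainedModel} of kind \code{dc_bilstm}.
#' @export
trainDCBiLSTM <- function(hX, eX, labels, valH = NULL, valE = NULL,
                          valLabels = NULL, config = list(), seed = 1L,
                          verbose = FALSE) {
  nH <- if (is.matrix(hX)) nrow(hX) else dim(hX)[1]
  nE <- if (is.matrix(eX)) nrow(eX) else dim(eX)[1]
  if (nH != nE) stop("H and E channel inputs differ in sample count",
                     call. = FALSE)
  hidden <- config$hidden %||% 64L
  epochs <- config$epochs %||% 100L
  batch <- config$batch %||% 64L
  lr <- config$lr %||% 1e-3
  patience <- config$patience %||% 10L
  y <- encodeBinary(labels)
  pos <- positiveLabel(labels)
  config$negativeClass <- setdiff(sort(unique(as.character(labels))),
                                  pos)[1]
  hs <- toSequence(hX); es <- toSequence(eX)
  din <- ncol(hs[[1]])
  p <- initDCBiLSTM(din, hidden, seed)
  m1 <- adamInit(p); m2 <- adamInit(p)
  hasVal <- !is.null(valH)
  if (hasVal) {
    vh <- toSequence(valH); ve <- toSequence(valE)
    vy <- as.numeric(as.character(valLabels) == pos)
  }
  best <- list(loss = Inf, p = p, epoch = 0L)
  wait <- 0L; step <- 0L
  n <- nH
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / batch)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch + 1L):min(bi * batch, n)]
      fw <- dcForward(subsetSeq(hs, idx), subsetSeq(es, idx), p, hidden)
      g <- dcBackward(fw, y[idx], p, hidden)
      step <- step + 1L
      upd <- adamStep(p, g, m1, m2, step, lr = lr)
      p <- upd$p; m1 <- upd$m1; m2 <- upd$m2
    }
    monitor <- if (hasVal) {
      dcLoss(dcForward(vh, ve, p, hidden)$probs, vy)
    } else {
      dcLoss(dcForward(hs, es, p, hidden)$probs, y)
    }
    if (verbose)
      message(sprintf("epoch %d: %s loss %.4f", ep,
                      if (hasVal) "val" else "train", monitor))
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, p = p, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  new("TrainedModel", kind = "dc_bilstm",
      fit = list(params = best$p, hidden = hidden, din = din,
                 bestEpoch = best$epoch, bestLoss = best$loss),
      featureNames = if (is.matrix(hX) && !is.null(colnames(hX)))
        colnames(hX) else character(0),
      positiveClass = pos, config = config, seed = as.integer(seed))
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "TrainedModel", function(model, newdata, ...) {
  pos <- model@positiveClass
  if (model@kind == "dc_bilstm") {
    stopifnot(is.list(newdata), all(c("h", "e") %in% names(newdata)))
    nH <- if (is.matrix(newdata$h)) nrow(newdata$h) else dim(newdata$h)[1]
    if (nH == 0L)
      return(data.frame(score = numeric(0), label = character(0)))
    fw <- dcForward(toSequence(newdata$h), toSequence(newdata$e),
                    model@fit$params, model@fit$hidden)
    score <- fw$probs[, 2]
  } else {
    x <- if (is(newdata, "FosExperiment")) fosMatrix(newdata)
         else as.matrix(newdata)
    if (nrow(x) == 0L)
      return(data.frame(score = numeric(0), label = character(0)))
    if (!is.null(colnames(x)) && length(model@featureNames) &&
        !all(model@featureNames %in% colnames(x)))
      stop("newdata lacks the model's feature columns", call. = FALSE)
    if (!is.null(colnames(x)) && length(model@featureNames))
      x <- x[, model@featureNames, drop = FALSE]
    if (ncol(x) != length(model@featureNames))
      stop("feature dimension mismatch", call. = FALSE)
    score <- switch(model@kind,
      svm = {
        pr <- stats::predict(model@fit, x, probability = TRUE)
        attr(pr, "probabilities")[, pos]
      },
      lr = {
        df <- as.data.frame(x, check.names = FALSE)
        as.numeric(stats::predict(model@fit, newdata = df,
                                  type = "response"))
      },
      bagging = stats::predict(model@fit, x, type = "prob")[, pos],
      boosting = stats::predict(model@fit, xgboost::xgb.DMatrix(x)))
  }
  neg <- model@config$negativeClass %||% "negative"
  data.frame(score = as.numeric(score),
             label = ifelse(score >= 0.5, pos, neg),
             stringsAsFactors = FALSE)
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel kind:", object@kind,
      "| positive class:", object@positiveClass,
      "| seed:", object@seed, "\n")
  if (length(object@featureNames))
    cat("  features:", paste(object@featureNames, collapse = ", "), "\n")
  if (object@kind == "dc_bilstm")
    cat(sprintf("  hidden=%d, best epoch %d (monitored loss %.4f)\n",
                object@fit$hidden, object@fit$bestEpoch, object@fit$bestLoss))
})
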