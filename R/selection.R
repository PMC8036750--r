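#' Recursive feature elimination with a gradient-boosting baseline
#'
#' Iteratively fits a gradient-boosting classifier (xgboost; 100 trees,
#' depth 3, learning rate 0.1, single thread) and removes the feature with
#' the smallest total importance (gain) each round until \code{k} features
#' remain, emitting the full elimination-order ranking (rank 1 = eliminated
#' first / weakest; the maximum rank = strongest). Ties in importance are
#' broken by removing the lexicographically last name, so the procedure is
#' fully deterministic given the seed.
#'
#' When the columns are dual-channel (\code{h_*} / \code{e_*} prefixes) the
#' elimination operates on feature \emph{families}: the H and E columns of
#' a family share its pooled (summed) importance and are eliminated
#' together, reconciling "five features out of six" with dual-channel
#' learning. Columns without channel prefixes are treated as singleton
#' families.
#'
#' @param x samples-by-features numeric matrix (or
#'   \linkS4class{FosExperiment}, whose scaled train matrix is used).
#' @param labels binary class labels aligned with the rows of \code{x}.
#' @param k number of features (families) to keep.
#' @param seed integer RNG seed for the baseline fits.
#' @param nrounds,maxDepth,eta baseline gradient-boosting hyperparameters.
#' @return data.frame with one row per family: \code{feature}, \code{rank}
#'   (permutation of 1..n, larger = stronger), \code{keep} (exactly k TRUE).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 100); colnames(x) <- paste0("f", 1:6)
#' y <- ifelse(x[, 1] > 0, "a", "b")
#' rfeRank(x, y, k = 5, seed = 1)
#' @export
rfeRank <- function(x, labels, k = 5L, seed = 1L,
                    nrounds = 100L, maxDepth = 3L, eta = 0.1) {
  if (is(x, "FosExperiment")) {
    labels <- x$class_label
    x <- fosMatrix(x)
  }
  x <- as.matrix(x)
  fam <- featureFamilies(colnames(x))
  families <- unique(fam)
  if (k > length(families))
    stop(sprintf("k = %d exceeds the %d feature families", k,
                 length(families)), call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  y <- encodeBinary(labels)
  active <- families
  rank <- integer(0)
  elimOrder <- character(0)
  set.seed(seed)
  while (length(active) > 1L) {
    cols <- which(fam %in% active)
    imp <- xgbImportance(x[, cols, drop = FALSE], y, nrounds, maxDepth, eta)
    famImp <- vapply(active, function(f)
      sum(imp[fam[cols] == f]), numeric(1))
    # weakest family out; ties -> lexicographically last name
    weakest <- active[famImp == min(famImp)]
    drop <- sort(weakest)[length(weakest)]
    elimOrder <- c(elimOrder, drop)
    active <- setdiff(active, drop)
    if (length(active) == 1L) elimOrder <- c(elimOrder, active)
  }
  if (length(families) == 1L) elimOrder <- families
  res <- data.frame(feature = elimOrder,
                    rank = seq_along(elimOrder),
                    stringsAsFactors = FALSE)
  res$keep <- res$rank > length(families) - k
  res[order(-res$rank), , drop = FALSE]
}

# h_energy/e_energy -> family "energy"; unprefixed columns are themselves
featureFamilies <- function(nms) {
  if (is.null(nms)) stop("feature columns must be named", call. = FALSE)
  sub("^[he]_", "", nms)
}

encodeBinary <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) < 2L)
    stop("labels contain a single class", call. = FALSE)
  if (length(lv) > 2L)
    stop("binary classification requires exactly 2 classes", call. = FALSE)
  as.numeric(as.character(labels) == positiveLabel(lv))
}

# fixed positive-class convention: malignant / grade5 / else the 2nd level
positiveLabel <- function(levels) {
  lv <- sort(unique(as.character(levels)))
  if ("malignant" %in% lv) return("malignant")
  if ("grade5" %in% lv) return("grade5")
  lv[length(lv)]
}

xgbImportance <- function(x, y, nrounds, maxDepth, eta) {
  d <- xgboost::xgb.DMatrix(x, label = y)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = maxDepth,
                  eta = eta, nthread = 1),
    data = d, nrounds = nrounds, verbose = 0)
  tab <- xgboost::xgb.importance(model = fit)
  imp <- setNames(rep(0, ncol(x)), colnames(x))
  imp[tab$Feature] <- tab$Gain  # features never used keep importance 0
  imp
}

#' One-way ANOVA with eta-squared effect size
#'
#' Standard one-way decomposition of a feature across groups:
#' \code{SS_total = SS_between + SS_within}, F = (SS_between/df_b) /
#' (SS_within/df_w), and the effect size \eqn{\eta^2 =
#' SS_{between}/SS_{total}}. The effect is categorized by the conventional
#' thresholds 0.01 (small), 0.06 (medium) and 0.14 (large); values below
#' 0.01 are still reported as "small".
#'
#' @param values numeric feature vector.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return one-row data.frame: f_value, p_value, ss_effect, ss_total,
#'   eta_squared, effect_category.
#' @examples
#' anovaEffect(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' @export
anovaEffect <- function(values, groups) {
  groups <- as.factor(groups)
  cnt <- table(groups)
  if (length(cnt) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(cnt < 2L))
    stop("every group needs at least 2 observations", call. = FALSE)
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(cnt * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  sst <- ssb + ssw
  dfb <- length(cnt) - 1L
  dfw <- length(values) - length(cnt)
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / dfb) / (ssw / dfw)
  }
  p <- if (is.infinite(f)) 0 else pf(f, dfb, dfw, lower.tail = FALSE)
  eta2 <- if (sst == 0) 0 else ssb / sst
  cat_ <- if (eta2 >= 0.14) "large" else if (eta2 >= 0.06) "medium"
          else "small"
  data.frame(f_value = f, p_value = p, ss_effect = ssb, ss_total = sst,
             eta_squared = eta2, effect_category = cat_,
             stringsAsFactors = FALSE)
}

#' Two-step feature selection: RFE then ANOVA validation
#'
#' Runs [rfeRank()] on the training partition, keeps the top-k feature
#' families, then validates each kept family by one-way ANOVA across the
#' class groups. The ANOVA runs per channel column and the family is
#' judged by its stronger channel (larger eta squared); pooling the H and
#' E values instead would let a family whose channels shift in opposite
#' directions cancel to a null effect despite being highly
#' discriminative. Families whose best channel has p >= alpha are
#' dropped; errors rather than guessing if the filter would leave no
#' feature.
#'
#' @param x a \linkS4class{FosExperiment} or samples-by-features matrix.
#' @param labels class labels (taken from the object when \code{x} is a
#'   FosExperiment).
#' @param k families to keep in the RFE step (default 5).
#' @param alpha ANOVA significance threshold (default 0.05).
#' @param seed RNG seed for the RFE baseline.
#' @return list with \code{kept} (character vector of kept family names),
#'   \code{columns} (the kept feature columns, both channels),
#'   \code{ranking} (the RFE table) and \code{report} (per kept family:
#'   the judging channel column, F, p, eta squared, category).
#' @export
selectFeatures <- function(x, labels = NULL, k = 5L, alpha = 0.05,
                           seed = 1L) {
  if (is(x, "FosExperiment")) {
    tr <- x[, x$partition == "train"]
    mat <- fosMatrix(tr)
    labels <- tr$class_label
  } else {
    mat <- as.matrix(x)
    if (is.null(labels)) stop("labels required for matrix input",
                              call. = FALSE)
  }
  ranking <- rfeRank(mat, labels, k = k, seed = seed)
  fam <- featureFamilies(colnames(mat))
  kept <- ranking$feature[ranking$keep]
  rows <- lapply(kept, function(f) {
    cols <- which(fam == f)
    per <- lapply(cols, function(j) anovaEffect(mat[, j], labels))
    best <- which.max(vapply(per, function(r) r$eta_squared, numeric(1)))
    cbind(data.frame(feature = f,
                     channel = colnames(mat)[cols][best],
                     stringsAsFactors = FALSE),
          per[[best]])
  })
  report <- do.call(rbind, rows)
  pass <- report$p_value < alpha
  if (!any(pass)) {
    stop("no RFE-selected feature passes the ANOVA filter (alpha = ",
         alpha, "); diagnostic report:\n",
         paste(utils::capture.output(print(report)), collapse = "\n"),
         call. = FALSE)
  }
  keptFinal <- report$feature[pass]
  # kept columns ordered by decreasing RFE rank (strongest first)
  ord <- ranking$feature[ranking$feature %in% keptFinal]
  cols <- unlist(lapply(ord, function(f) colnames(mat)[fam == f]))
  list(kept = ord, columns = cols, ranking = ranking,
       report = report[order(-ranking$rank[match(report$feature,
                                                 ranking$feature)]), ])
}
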