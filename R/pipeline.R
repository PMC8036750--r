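#' Build a pipeline run configuration
#'
#' Collects every stage's parameters with the defaults used throughout the
#' package: 256x256 synthetic ROIs in two classes, gamma 1.0 (no-op unless
#' overridden), 64x64 non-overlapping patches, Ruifrok-Johnston
#' deconvolution with a global [0,3] quantization range, 256-bin FOS
#' features standardized on the train partition, RFE(k = 5) + ANOVA
#' selection, and all five classifiers. One master seed deterministically
#' derives a seed per stage (\code{master + 7919 * stage_index}, kept below
#' 2^31), so a rerun with the same configuration reproduces every artifact.
#'
#' @param outputDir base output directory.
#' @param runId subdirectory name for this run.
#' @param seed master integer seed.
#' @param nPerClass synthetic ROIs per class (250 gives the 500-ROI layout:
#'   8000 patches split 5120/1280/1600).
#' @param classes two class labels understood by [synthParams()], or any
#'   two labels present in a supplied manifest.
#' @param imageSize synthetic ROI edge (pixels).
#' @param manifestPath optional existing manifest CSV
#'   (image_path,roi_id,class); when given the synth stage is skipped and
#'   image paths are resolved relative to the manifest's directory.
#' @param gamma power-law exponent for [gammaCorrect()].
#' @param resizeTarget optional square resize target before patching.
#' @param backgroundThreshold mean-OD background cutoff; 0 disables
#'   filtering.
#' @param keepTopK optional number of best patches kept by tissue content.
#' @param fractions train/val/test ROI fractions.
#' @param kFeatures families kept by RFE.
#' @param alpha ANOVA significance threshold.
#' @param models character vector among svm, lr, bagging, boosting,
#'   dc_bilstm.
#' @param bilstm list of DC-BiLSTM settings (hidden, epochs, batch, lr,
#'   patience, inputMode "feature" or "patch_rows").
#' @param quantRange global concentration quantization range (OD units).
#' @param nbins FOS histogram bins.
#' @param task hypothesis task label: internal_bm, internal_grade or
#'   external_bm (default inferred from \code{classes}).
#' @return a named list (class "pipelineConfig").
#' @export
pipelineConfig <- function(outputDir = tempfile("stainfos_run_"),
                           runId = "run1", seed = 1L,
                           nPerClass = 250L,
                           classes = c("benign", "malignant"),
                           imageSize = 256L, manifestPath = NULL,
                           gamma = 1.0, resizeTarget = NULL,
                           backgroundThreshold = 0, keepTopK = NULL,
                           fractions = c(train = 0.64, val = 0.16,
                                         test = 0.20),
                           kFeatures = 5L, alpha = 0.05,
                           models = c("svm", "lr", "bagging", "boosting",
                                      "dc_bilstm"),
                           bilstm = list(), quantRange = c(0, 3),
                           nbins = 256L, task = NULL) {
  bdef <- list(hidden = 64L, epochs = 100L, batch = 64L, lr = 1e-3,
               patience = 10L, inputMode = "feature")
  bilstm <- utils::modifyList(bdef, bilstm)
  if (is.null(task)) {
    task <- if (setequal(classes, c("grade3", "grade5"))) "internal_grade"
            else "internal_bm"
  }
  cfg <- list(outputDir = outputDir, runId = runId, seed = as.integer(seed),
              nPerClass = as.integer(nPerClass), classes = classes,
              imageSize = as.integer(imageSize),
              manifestPath = manifestPath, gamma = gamma,
              resizeTarget = resizeTarget,
              backgroundThreshold = backgroundThreshold,
              keepTopK = keepTopK, fractions = fractions,
              kFeatures = as.integer(kFeatures), alpha = alpha,
              models = models, bilstm = bilstm, quantRange = quantRange,
              nbins = as.integer(nbins), task = task)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipelineConfig()] arguments.
#' @return a pipelineConfig list.
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fractions)) y$fractions <- unlist(y$fractions)
  if (!is.null(y$quantRange)) y$quantRange <- unlist(y$quantRange)
  if (!is.null(y$classes)) y$classes <- unlist(y$classes)
  if (!is.null(y$models)) y$models <- unlist(y$models)
  do.call(pipelineConfig, y)
}

STAGES <- c("synth", "preprocess", "features", "select", "train",
            "evaluate")

stageSeed <- function(cfg, stage) {
  i <- match(stage, STAGES)
  as.integer((cfg$seed + 7919 * i) %% (.Machine$integer.max - 1L))
}

runDir <- function(cfg) file.path(cfg$outputDir, cfg$runId)

needArtifact <- function(cfg, file, stage) {
  p <- file.path(runDir(cfg), file)
  if (!file.exists(p))
    stop(sprintf("stage '%s' requires missing upstream artifact: %s",
                 stage, p), call. = FALSE)
  p
}

readManifest <- function(cfg, stage = "preprocess") {
  if (!is.null(cfg$manifestPath)) {
    m <- read.csv(cfg$manifestPath, stringsAsFactors = FALSE)
    m$image_dir <- dirname(normalizePath(cfg$manifestPath))
  } else {
    p <- needArtifact(cfg, "manifest.csv", stage)
    m <- read.csv(p, stringsAsFactors = FALSE)
    m$image_dir <- runDir(cfg)
  }
  m
}

# read + gamma + optional resize, per the run configuration
preprocessImage <- function(cfg, manifestRow) {
  px <- readTissueImage(file.path(manifestRow$image_dir,
                                  manifestRow$image_path))
  if (cfg$gamma != 1) px <- gammaCorrect(px, cfg$gamma)
  if (!is.null(cfg$resizeTarget)) px <- resizeImage(px, cfg$resizeTarget)
  px
}

#' Run one pipeline stage
#'
#' Executes a single stage against the run directory, reading the previous
#' stage's persisted artifacts and overwriting only its own outputs, so any
#' stage can be re-run in isolation. Missing upstream artifacts raise an
#' explicit dependency error naming the file.
#'
#' Stages and their artifacts (under \code{outputDir/runId/}):
#' \describe{
#'   \item{synth}{\code{images/}, \code{manifest.csv}}
#'   \item{preprocess}{\code{patches.csv} — patch index (patch_id, roi_id,
#'     row0, col0, class, partition, mean_od) after ROI-level splitting and
#'     optional background filtering; pixels are re-derived
#'     deterministically from the images when needed}
#'   \item{features}{\code{features.csv} — dual-channel FOS table}
#'   \item{select}{\code{selection.csv}, \code{selected.json}}
#'   \item{train}{\code{models.rds}}
#'   \item{evaluate}{\code{metrics.csv}, \code{confusion_<model>.csv},
#'     \code{roc_<model>.csv}, \code{hypothesis.csv}, \code{summary.json}}
#' }
#'
#' @param stage one of synth, preprocess, features, select, train,
#'   evaluate.
#' @param config a [pipelineConfig()].
#' @return the stage's main result, invisibly (also persisted to disk).
#' @export
runStage <- function(stage = STAGES, config) {
  stage <- match.arg(stage)
  cfg <- config
  dir.create(runDir(cfg), recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(stage,
    synth = stageSynth(cfg),
    preprocess = stagePreprocess(cfg),
    features = stageFeatures(cfg),
    select = stageSelect(cfg),
    train = stageTrain(cfg),
    evaluate = stageEvaluate(cfg))
  message(sprintf("[%s] stage '%s' done in %.1fs",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

stageSynth <- function(cfg) {
  if (!is.null(cfg$manifestPath)) {
    message("synth: external manifest supplied, nothing to generate")
    return(invisible(NULL))
  }
  generateDataset(runDir(cfg), cfg$nPerClass, cfg$classes,
                  seed = stageSeed(cfg, "synth"),
                  imageSize = cfg$imageSize)
}

stagePreprocess <- function(cfg) {
  manifest <- readManifest(cfg)
  split <- splitRois(manifest[, c("roi_id", "class")],
                     fractions = cfg$fractions,
                     seed = stageSeed(cfg, "preprocess"))
  manifest <- merge(manifest, split[, c("roi_id", "partition")],
                    by = "roi_id", sort = FALSE)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    px <- preprocessImage(cfg, manifest[i, ])
    ps <- extractPatches(px, manifest$roi_id[i], manifest$class[i])
    info <- patchInfo(ps)
    info$partition <- manifest$partition[i]
    info$mean_od <- patchMeanOD(ps)
    rows[[i]] <- info
  }
  idx <- do.call(rbind, rows)
  if (cfg$backgroundThreshold > 0 || !is.null(cfg$keepTopK)) {
    keep <- idx$mean_od >= cfg$backgroundThreshold
    idx <- idx[keep, , drop = FALSE]
    idx <- idx[order(-idx$mean_od, idx$patch_id), , drop = FALSE]
    if (!is.null(cfg$keepTopK)) {
      if (cfg$keepTopK > nrow(idx))
        stop(sprintf("keepTopK = %d exceeds the %d surviving patches",
                     cfg$keepTopK, nrow(idx)), call. = FALSE)
      idx <- idx[seq_len(cfg$keepTopK), , drop = FALSE]
    }
  }
  write.csv(idx, file.path(runDir(cfg), "patches.csv"), row.names = FALSE,
            quote = FALSE)
  idx
}

stageFeatures <- function(cfg) {
  idxPath <- needArtifact(cfg, "patches.csv", "features")
  manifest <- readManifest(cfg, "features")
  idx <- read.csv(idxPath, stringsAsFactors = FALSE)
  perRoi <- split(idx, idx$roi_id)
  rows <- vector("list", length(perRoi))
  for (k in seq_along(perRoi)) {
    sub <- perRoi[[k]]
    mrow <- manifest[manifest$roi_id == sub$roi_id[1], , drop = FALSE][1, ]
    px <- preprocessImage(cfg, mrow)
    ps <- extractPatches(px, mrow$roi_id, mrow$class)
    ps <- ps[sub$patch_id]
    rec <- extractDualChannelFeatures(ps, nbins = cfg$nbins,
                                      quantRange = cfg$quantRange)
    rec$partition <- sub$partition[match(rec$patch_id, sub$patch_id)]
    rows[[k]] <- rec
  }
  records <- do.call(rbind, rows)
  records$partition <- factor(records$partition,
                              levels = c("train", "val", "test"))
  fe <- buildFeatureTable(records)
  writeFeatureCSV(fe, file.path(runDir(cfg), "features.csv"))
  fe
}

stageSelect <- function(cfg) {
  fe <- readFeatureCSV(needArtifact(cfg, "features.csv", "select"))
  sel <- selectFeatures(fe, k = cfg$kFeatures, alpha = cfg$alpha,
                        seed = stageSeed(cfg, "select"))
  selTab <- merge(sel$ranking, sel$report, by = "feature", all.x = TRUE,
                  sort = FALSE)
  write.csv(selTab[order(-selTab$rank), ],
            file.path(runDir(cfg), "selection.csv"), row.names = FALSE)
  jsonlite::write_json(list(kept = sel$kept, columns = sel$columns),
                       file.path(runDir(cfg), "selected.json"))
  sel
}

bilstmInputs <- function(cfg, fe, kept, part) {
  sub <- fe[, fe$partition %in% part]
  mode <- cfg$bilstm$inputMode
  if (mode == "feature") {
    m <- fosMatrix(sub)
    list(h = m[, paste0("h_", kept), drop = FALSE],
         e = m[, paste0("e_", kept), drop = FALSE],
         labels = sub$class_label)
  } else {
    manifest <- readManifest(cfg)
    info <- SummarizedExperiment::colData(sub)
    n <- nrow(info)
    h <- array(0, c(n, 64, 64)); e <- array(0, c(n, 64, 64))
    for (roi in unique(info$roi_id)) {
      mrow <- manifest[manifest$roi_id == roi, , drop = FALSE][1, ]
      ps <- extractPatches(preprocessImage(cfg, mrow), roi, mrow$class)
      sel <- which(info$roi_id == roi)
      for (j in sel) {
        dec <- deconvolveStains(patchPixels(ps, info$patch_id[j]),
                                quantRange = cfg$quantRange)
        h[j, , ] <- dec$h_quant / 255
        e[j, , ] <- dec$e_quant / 255
      }
    }
    list(h = h, e = e, labels = sub$class_label)
  }
}

stageTrain <- function(cfg) {
  fe <- readFeatureCSV(needArtifact(cfg, "features.csv", "train"))
  selPath <- needArtifact(cfg, "selected.json", "train")
  sel <- jsonlite::read_json(selPath, simplifyVector = TRUE)
  seed <- stageSeed(cfg, "train")
  tr <- fe[, fe$partition == "train"]
  xTr <- fosMatrix(tr)[, sel$columns, drop = FALSE]
  models <- list()
  for (kind in cfg$models) {
    if (kind == "dc_bilstm") {
      trIn <- bilstmInputs(cfg, fe, sel$kept, "train")
      vaIn <- bilstmInputs(cfg, fe, sel$kept, "val")
      hasVal <- length(vaIn$labels) > 0
      models[[kind]] <- trainDCBiLSTM(
        trIn$h, trIn$e, trIn$labels,
        valH = if (hasVal) vaIn$h, valE = if (hasVal) vaIn$e,
        valLabels = if (hasVal) vaIn$labels,
        config = cfg$bilstm, seed = seed)
    } else {
      models[[kind]] <- trainClassifier(xTr, tr$class_label, kind,
                                        seed = seed)
    }
  }
  saveRDS(models, file.path(runDir(cfg), "models.rds"))
  models
}

stageEvaluate <- function(cfg) {
  fe <- readFeatureCSV(needArtifact(cfg, "features.csv", "evaluate"))
  sel <- jsonlite::read_json(needArtifact(cfg, "selected.json", "evaluate"),
                             simplifyVector = TRUE)
  models <- readRDS(needArtifact(cfg, "models.rds", "evaluate"))
  te <- fe[, fe$partition == "test"]
  feats <- fosMatrix(te)[, sel$columns, drop = FALSE]
  seqs <- if ("dc_bilstm" %in% names(models))
    bilstmInputs(cfg, fe, sel$kept, "test")[c("h", "e")] else NULL
  cmp <- comparativeReport(models,
                           list(features = feats, sequences = seqs),
                           te$class_label)
  rd <- runDir(cfg)
  write.csv(cmp$table, file.path(rd, "metrics.csv"), row.names = FALSE)
  for (nm in names(cmp$confusions))
    write.csv(as.data.frame(cmp$confusions[[nm]]),
              file.path(rd, paste0("confusion_", nm, ".csv")))
  recalls <- setNames(cmp$table$recall, cmp$table$model)
  best <- which.max(recalls)
  hyp <- checkHypothesis(setNames(max(recalls, na.rm = TRUE), cfg$task),
                         tasks = cfg$task)
  write.csv(hyp, file.path(rd, "hypothesis.csv"), row.names = FALSE)
  summary <- list(task = cfg$task, n_test = ncol(te),
                  best_model = names(recalls)[best],
                  best_recall = unname(recalls[best]),
                  metrics = cmp$table,
                  hypothesis_pass = all(hyp$pass),
                  config_md5 = configHash(cfg))
  jsonlite::write_json(summary, file.path(rd, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(report = cmp, hypothesis = hyp, summary = summary)
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes every stage in order (synthesis or manifest ingestion, gamma
#' correction and patching with ROI-level splitting, stain deconvolution
#' and dual-channel FOS features, two-step feature selection, training of
#' the configured classifiers, comparative evaluation with confusion
#' matrices, ROC/AUC and the recall hypothesis check), persisting each
#' stage's artifacts under \code{outputDir/runId/} so stages can be
#' re-run independently with [runStage()].
#'
#' @param config a [pipelineConfig()].
#' @return the evaluate stage result: list(report, hypothesis, summary).
#' @export
runPipeline <- function(config) {
  dir.create(runDir(config), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(runDir(config),
                                              "config.yaml"))
  out <- NULL
  for (st in STAGES) {
    out <- tryCatch(runStage(st, config), error = function(err)
      stop(sprintf("pipeline halted at stage '%s': %s", st,
                   conditionMessage(err)), call. = FALSE))
  }
  out
}
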