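#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm runif sd var aov pf pnorm quantile setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Optical-density stain basis for colour deconvolution
#'
#' A 3x3 matrix of unit-norm optical-density vectors over (R, G, B): one row
#' per stain (Hematoxylin, Eosin) plus a residual row completing the basis.
#' Pixel OD vectors are linear combinations of these rows weighted by stain
#' concentration (Beer-Lambert mixing), so concentrations are recovered by
#' multiplying OD by the matrix inverse.
#'
#' @slot od 3x3 numeric matrix, rows named "H", "E", "R", each of unit
#'   Euclidean norm; columns correspond to the R, G, B channels.
#' @slot name character scalar identifying the basis.
#'
#' @seealso [ruifrokHE()], [deconvolveStains()]
#' @exportClass StainMatrix
setClass("StainMatrix",
  representation(od = "matrix", name = "character"))

setValidity("StainMatrix", function(object) {
  m <- object@od
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    return("'od' must be a numeric 3x3 matrix")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-6))
    return("each stain vector must have unit Euclidean norm (tol 1e-6)")
  d <- det(m)
  if (!is.finite(d) || abs(d) < 1e-8)
    return("stain matrix is singular or near-singular")
  if (!identical(rownames(m), c("H", "E", "R")))
    return("rows must be named H, E, R")
  TRUE
})

#' A set of 64x64 RGB tissue patches with provenance
#'
#' Container for non-overlapping patches tiled from parent region-of-interest
#' (ROI) images. Pixel data are stored as a list of integer arrays
#' (64 x 64 x 3, values in 0..255); per-patch provenance (parent ROI, tile
#' offsets, class label, partition) lives in a data.frame aligned with the
#' pixel list.
#'
#' @slot pixels list of 64x64x3 integer arrays in [0, 255].
#' @slot info data.frame with one row per patch: \code{patch_id},
#'   \code{roi_id}, \code{row0}, \code{col0} (0-based top-left offsets,
#'   multiples of the patch size), \code{class_label}, and optionally
#'   \code{partition}.
#' @slot patchSize integer patch edge length (64 by default).
#'
#' @seealso [extractPatches()], [filterBackground()]
#' @exportClass PatchSet
setClass("PatchSet",
  representation(pixels = "list", info = "data.frame", patchSize = "integer"))

setValidity("PatchSet", function(object) {
  if (length(object@pixels) != nrow(object@info))
    return("pixel list and info table lengths differ")
  need <- c("patch_id", "roi_id", "row0", "col0")
  if (!all(need %in% names(object@info)))
    return(paste("info must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@info$patch_id))
    return("patch_id values must be unique")
  ps <- object@patchSize
  if (length(object@pixels)) {
    d <- dim(object@pixels[[1]])
    if (!identical(d, c(ps, ps, 3L)))
      return(sprintf("patch arrays must be %d x %d x 3", ps, ps))
  }
  TRUE
})

#' Dual-channel first-order-statistic feature container
#'
#' A \linkS4class{SummarizedExperiment} holding the 12-dimensional dual-channel
#' feature matrix (6 first-order statistics per stain channel) for a set of
#' patches: rows are features (\code{h_energy} ... \code{e_uniformity}),
#' columns are patches. Two assays are kept: \code{raw} and \code{scaled}
#' (z-scores using means/sds fitted on the training partition only, stored in
#' \code{metadata()$scaling}). Column data carry \code{patch_id},
#' \code{roi_id}, \code{class_label} and \code{partition}.
#'
#' @seealso [buildFeatureTable()], [fosMatrix()]
#' @exportClass FosExperiment
setClass("FosExperiment", contains = "SummarizedExperiment")

setValidity("FosExperiment", function(object) {
  if (!all(c("raw", "scaled") %in% SummarizedExperiment::assayNames(object)))
    return("assays 'raw' and 'scaled' are required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("patch_id", "roi_id", "class_label", "partition")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  TRUE
})

#' A fitted binary tissue classifier
#'
#' Wraps one of the five supported model kinds (\code{svm}, \code{lr},
#' \code{bagging}, \code{boosting}, \code{dc_bilstm}) together with the
#' feature names it was trained on, its configuration and seed, and the
#' positive class label, so that every model is scored through the single
#' [predictScores()] interface.
#'
#' @slot kind character; one of svm, lr, bagging, boosting, dc_bilstm.
#' @slot fit the underlying fitted object (library-specific, or the BiLSTM
#'   parameter list).
#' @slot featureNames character vector of feature columns (classical models)
#'   or per-channel feature families (DC-BiLSTM).
#' @slot positiveClass character; label scored as the positive class
#'   (malignant, or grade5).
#' @slot config list of hyperparameters used.
#' @slot seed integer RNG seed the fit was run under.
#'
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(kind = "character", fit = "ANY", featureNames = "character",
                 positiveClass = "character", config = "list",
                 seed = "integer"))

setValidity("TrainedModel", function(object) {
  kinds <- c("svm", "lr", "bagging", "boosting", "dc_bilstm")
  if (!(object@kind %in% kinds))
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (length(object@seed) != 1L) return("seed must be a single integer")
  TRUE
})
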