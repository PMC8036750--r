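#' @rdname StainMatrix-class
#' @param x a \linkS4class{StainMatrix}.
#' @return \code{odMatrix} returns the 3x3 numeric OD basis matrix.
#' @export
setGeneric("odMatrix", function(x) standardGeneric("odMatrix"))

#' @rdname PatchSet-class
#' @param x a \linkS4class{PatchSet}.
#' @return \code{patchInfo} returns the per-patch provenance data.frame.
#' @export
setGeneric("patchInfo", function(x) standardGeneric("patchInfo"))

#' @rdname PatchSet-class
#' @param i patch index or patch_id.
#' @return \code{patchPixels} returns one 64x64x3 integer array.
#' @export
setGeneric("patchPixels", function(x, i) standardGeneric("patchPixels"))

#' @rdname FosExperiment-class
#' @param x a \linkS4class{FosExperiment}.
#' @param scaled logical; return the train-standardized assay (default) or
#'   the raw feature values.
#' @return \code{fosMatrix} returns a samples-by-features numeric matrix
#'   (transposed assay, ready for model fitting).
#' @export
setGeneric("fosMatrix", function(x, scaled = TRUE) standardGeneric("fosMatrix"))

#' Score samples with a fitted tissue classifier
#'
#' Returns the positive-class probability for each sample, plus hard labels
#' at the 0.5 threshold. Deterministic given the fitted model.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param newdata for classical kinds, a samples-by-features matrix (or a
#'   \linkS4class{FosExperiment}); for \code{dc_bilstm}, a list with elements
#'   \code{h} and \code{e}, each samples-by-k matrices of per-channel feature
#'   sequences.
#' @param ... unused.
#' @return data.frame with columns \code{score} (probability of the positive
#'   class, in [0,1]) and \code{label} (predicted class at threshold 0.5).
#' @export
setGeneric("predictScores", function(model, newdata, ...)
  standardGeneric("predictScores"))
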