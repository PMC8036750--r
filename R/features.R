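FOS_NAMES <- c("energy", "entropy", "kurtosis", "skewness", "variance",
               "uniformity")

#' First-order-statistic radiomic features of one channel patch
#'
#' Computes the six histogram/moment features of a quantized stain-channel
#' patch, with N pixels x_j and normalized histogram p(i) over \code{nbins}
#' gray levels:
#' \itemize{
#'   \item energy: sum of squared intensities, \eqn{\sum_j x_j^2}
#'   \item entropy: \eqn{-\sum_i p(i) \log_2 p(i)} over nonzero bins (bits)
#'   \item kurtosis: non-excess moment ratio \eqn{m_4 / m_2^2}
#'   \item skewness: \eqn{m_3 / m_2^{3/2}}
#'   \item variance: population variance \eqn{m_2 = \frac{1}{N}\sum_j (x_j-\mu)^2}
#'   \item uniformity: \eqn{\sum_i p(i)^2}
#' }
#' A constant patch has variance 0, entropy 0, uniformity 1, and skewness
#' and kurtosis defined as 0 by convention. These are first-order features:
#' they depend only on the intensity distribution, never on pixel positions.
#'
#' @param values numeric matrix/vector of quantized gray levels in
#'   [0, nbins - 1] (from [deconvolveStains()]'s \code{h_quant}/
#'   \code{e_quant}), or raw concentration values if a continuous route is
#'   wanted (the histogram then bins \code{floor(values)}).
#' @param nbins number of histogram bins (default 256, matching 8-bit
#'   quantization).
#' @return named numeric vector of the six features.
#' @examples
#' computeFOS(c(0, 0, 255, 255))
#' @export
computeFOS <- function(values, nbins = 256L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n == 0L) stop("empty patch", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  energy <- sum(x^2)
  if (m2 == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  counts <- tabulate(pmin(nbins - 1L, pmax(0L, floor(x))) + 1L, nbins)
  p <- counts / n
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)
  c(energy = energy, entropy = entropy, kurtosis = kurt, skewness = skew,
    variance = m2, uniformity = uniformity)
}

#' Dual-channel FOS records for a patch set
#'
#' Deconvolves every patch into Hematoxylin and Eosin channels and computes
#' the six FOS features per channel, yielding one 12-dimensional record per
#' patch (columns \code{h_energy} ... \code{e_uniformity}).
#'
#' @param patches a \linkS4class{PatchSet} (with a \code{partition} column
#'   in its info if the table is to be standardized downstream).
#' @param stainMatrix the \linkS4class{StainMatrix} for deconvolution.
#' @param nbins histogram bins for [computeFOS()].
#' @param quantRange global concentration range for 8-bit quantization.
#' @param quantized compute features on the 8-bit quantized channel maps
#'   (default) or on the raw concentration maps.
#' @return data.frame: patch_id, roi_id, class_label, (partition,) then the
#'   12 feature columns.
#' @export
extractDualChannelFeatures <- function(patches, stainMatrix = ruifrokHE(),
                                       nbins = 256L, quantRange = c(0, 3),
                                       quantized = TRUE) {
  info <- patchInfo(patches)
  feats <- matrix(NA_real_, nrow = length(patches), ncol = 12L)
  colnames(feats) <- c(paste0("h_", FOS_NAMES), paste0("e_", FOS_NAMES))
  for (i in seq_len(length(patches))) {
    dec <- deconvolveStains(patchPixels(patches, i), stainMatrix, quantRange)
    if (quantized) {
      feats[i, ] <- c(computeFOS(dec$h_quant, nbins),
                      computeFOS(dec$e_quant, nbins))
    } else {
      feats[i, ] <- c(computeFOS(dec$h, nbins), computeFOS(dec$e, nbins))
    }
  }
  cbind(info, as.data.frame(feats))
}

#' Assemble the dual-channel feature table
#'
#' Builds a \linkS4class{FosExperiment} (a SummarizedExperiment with
#' features as rows and patches as columns) from per-patch dual-channel
#' records. Z-score standardization parameters are fitted on the train
#' partition only and applied to all partitions; columns with zero training
#' sd are left at 0 rather than divided by 0.
#'
#' @param records data.frame from [extractDualChannelFeatures()], with a
#'   \code{partition} column when \code{standardize = TRUE}.
#' @param standardize fit and apply train-partition z-scores (default TRUE).
#' @return a \linkS4class{FosExperiment} with assays \code{raw} and
#'   \code{scaled}; \code{metadata()$scaling} holds the train means/sds.
#' @export
buildFeatureTable <- function(records, standardize = TRUE) {
  featCols <- c(paste0("h_", FOS_NAMES), paste0("e_", FOS_NAMES))
  stopifnot(all(featCols %in% names(records)))
  if (!("partition" %in% names(records)))
    records$partition <- factor("train", levels = c("train", "val", "test"))
  raw <- t(as.matrix(records[, featCols]))
  colnames(raw) <- records$patch_id
  if (standardize) {
    trainIdx <- records$partition == "train"
    if (!any(trainIdx))
      stop("standardization requires a train partition", call. = FALSE)
    mu <- rowMeans(raw[, trainIdx, drop = FALSE])
    sdv <- apply(raw[, trainIdx, drop = FALSE], 1, sd)
    scaled <- (raw - mu) / ifelse(sdv > 0, sdv, 1)
    scaled[sdv == 0, ] <- 0
    scaling <- list(mean = mu, sd = sdv)
  } else {
    scaled <- raw
    scaling <- NULL
  }
  cd <- S4Vectors::DataFrame(
    patch_id = records$patch_id, roi_id = records$roi_id,
    class_label = records$class_label,
    partition = records$partition, row.names = records$patch_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw, scaled = scaled), colData = cd,
    metadata = list(scaling = scaling))
  new("FosExperiment", se)
}

#' @rdname FosExperiment-class
#' @export
setMethod("fosMatrix", "FosExperiment", function(x, scaled = TRUE) {
  t(SummarizedExperiment::assay(x, if (scaled) "scaled" else "raw"))
})

setMethod("show", "FosExperiment", function(object) {
  cat("FosExperiment:", nrow(object), "features x", ncol(object),
      "patches\n")
  cat("  classes:  ",
      paste(names(table(object$class_label)), table(object$class_label),
            sep = "=", collapse = ", "), "\n")
  cat("  partition:",
      paste(names(table(object$partition)), table(object$partition),
            sep = "=", collapse = ", "), "\n")
})

#' Write / read a feature table as CSV
#'
#' Round-trips the raw feature values with provenance columns at full
#' precision (15 significant digits); header is
#' \code{patch_id,roi_id,class,partition,h_energy,...,e_uniformity}.
#'
#' @param x a \linkS4class{FosExperiment}.
#' @param path CSV path.
#' @return \code{writeFeatureCSV}: the path, invisibly;
#'   \code{readFeatureCSV}: a \linkS4class{FosExperiment}.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(patch_id = x$patch_id, roi_id = x$roi_id,
                   class = x$class_label, partition = x$partition,
                   t(SummarizedExperiment::assay(x, "raw")),
                   check.names = FALSE)
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.15g", v))
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @param standardize passed to [buildFeatureTable()].
#' @export
readFeatureCSV <- function(path, standardize = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "class"] <- "class_label"
  df$partition <- factor(df$partition, levels = c("train", "val", "test"))
  buildFeatureTable(df, standardize = standardize)
}
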