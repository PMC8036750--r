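#' Read an 8-bit RGB tissue image
#'
#' Reads PNG (via \pkg{png}) or TIFF (via \pkg{tiff}, if installed) into the
#' package's pixel convention: an integer array height x width x 3 with
#' values in [0, 255], row-major, top-left origin. Grayscale inputs are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return integer array H x W x 3.
#' @export
readTissueImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] == 1L) raw <- raw[, , c(1, 1, 1), drop = FALSE]
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  px <- array(as.integer(roundHalfUp(raw * 255)), dim = dim(raw))
  px
}

#' Write an 8-bit RGB image to PNG
#'
#' @param pixels integer array H x W x 3 in [0, 255].
#' @param path output .png path.
#' @return the path, invisibly.
#' @export
writeTissueImage <- function(pixels, path) {
  png::writePNG(pixels / 255, target = path)
  invisible(path)
}

# round-half-up; base round() is half-to-even
roundHalfUp <- function(x) floor(x + 0.5)

#' Power-law (gamma) contrast correction
#'
#' Maps every channel value v to \code{round(255 * (v/255)^gamma)} with
#' round-half-up, applied per channel. gamma = 1 is the identity; 0 and 255
#' are fixed points for any gamma. Monotone non-decreasing in v for any
#' gamma > 0.
#'
#' @param pixels integer array of 8-bit values (any shape).
#' @param gamma positive exponent; values < 1 brighten, > 1 darken.
#' @return integer array of the same shape, still in [0, 255].
#' @examples
#' gammaCorrect(array(64L, c(1, 1, 3)), gamma = 0.5)  # -> 128
#' @export
gammaCorrect <- function(pixels, gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a single positive number", call. = FALSE)
  out <- roundHalfUp(255 * (pixels / 255)^gamma)
  storage.mode(out) <- "integer"
  array(out, dim = dim(pixels))
}

#' Bilinear resize to a square target
#'
#' Bilinear resampling (via \pkg{EBImage}) to \code{target x target} pixels,
#' e.g. 2500 x 2500 external ROIs down to 2048 x 2048 before tiling. The
#' target must be divisible by the 64-pixel patch size.
#'
#' @param pixels integer array H x W x 3 in [0, 255].
#' @param target edge length in pixels; must be divisible by 64.
#' @return integer array target x target x 3.
#' @export
resizeImage <- function(pixels, target) {
  if (target %% 64L != 0L)
    stop("resize target must be divisible by the 64-pixel patch size",
         call. = FALSE)
  if (identical(dim(pixels)[1:2], c(as.integer(target), as.integer(target))))
    return(pixels)
  img <- EBImage::Image(pixels / 255, colormode = "Color")
  res <- EBImage::resize(img, w = target, h = target, filter = "bilinear")
  out <- roundHalfUp(EBImage::imageData(res) * 255)
  out[out < 0L] <- 0L; out[out > 255L] <- 255L
  storage.mode(out) <- "integer"
  out
}

#' Tile an image into non-overlapping 64x64 patches
#'
#' Returns \code{floor(H/64) * floor(W/64)} patches in row-major order
#' (left-to-right, then top-to-bottom); trailing remainder rows/columns that
#' do not fill a whole patch are discarded. Offsets are 0-based multiples of
#' the patch size, so re-assembling the patches by offset reproduces the
#' image exactly on divisible dimensions.
#'
#' @param pixels integer array H x W x 3, with H, W >= patchSize.
#' @param roiId character identifier of the parent ROI.
#' @param classLabel optional class label stored with every patch.
#' @param patchSize patch edge length, default 64.
#' @return a \linkS4class{PatchSet}.
#' @examples
#' img <- beerLambertForward(matrix(0.5, 256, 256), matrix(0.5, 256, 256))
#' length(extractPatches(img, "roi1"))  # 16
#' @export
extractPatches <- function(pixels, roiId, classLabel = NA_character_,
                           patchSize = 64L) {
  d <- dim(pixels)
  if (d[1] < patchSize || d[2] < patchSize)
    stop(sprintf("image (%d x %d) is smaller than the patch size %d",
                 d[1], d[2], patchSize), call. = FALSE)
  nr <- d[1] %/% patchSize
  nc <- d[2] %/% patchSize
  px <- vector("list", nr * nc)
  info <- data.frame(patch_id = character(nr * nc), roi_id = roiId,
                     row0 = 0L, col0 = 0L, class_label = classLabel,
                     stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nr)) {
    r0 <- (i - 1L) * patchSize
    for (j in seq_len(nc)) {
      c0 <- (j - 1L) * patchSize
      k <- k + 1L
      px[[k]] <- pixels[(r0 + 1L):(r0 + patchSize),
                        (c0 + 1L):(c0 + patchSize), , drop = FALSE]
      info$patch_id[k] <- sprintf("%s_r%04d_c%04d", roiId, r0, c0)
      info$row0[k] <- r0
      info$col0[k] <- c0
    }
  }
  new("PatchSet", pixels = px, info = info, patchSize = as.integer(patchSize))
}

#' Concatenate patch sets from several ROIs
#'
#' @param sets list of \linkS4class{PatchSet} objects with equal patch size.
#' @return a single \linkS4class{PatchSet}.
#' @export
combinePatchSets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  ps <- sets[[1]]@patchSize
  new("PatchSet",
      pixels = do.call(c, lapply(sets, function(s) s@pixels)),
      info = do.call(rbind, lapply(sets, function(s) s@info)),
      patchSize = ps)
}

#' @rdname PatchSet-class
#' @export
setMethod("patchInfo", "PatchSet", function(x) x@info)

#' @rdname PatchSet-class
#' @export
setMethod("patchPixels", "PatchSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@info$patch_id)
  x@pixels[[i]]
})

#' @rdname PatchSet-class
#' @param x a \linkS4class{PatchSet}.
#' @export
setMethod("length", "PatchSet", function(x) length(x@pixels))

#' @rdname PatchSet-class
#' @param i indices (integer, logical, or patch_id character).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$patch_id)
  new("PatchSet", pixels = x@pixels[i],
      info = x@info[i, , drop = FALSE], patchSize = x@patchSize)
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet of", length(object), "patches (",
      object@patchSize, "x", object@patchSize, ") from",
      length(unique(object@info$roi_id)), "ROI(s)\n")
  if (length(object)) print(head(object@info, 4))
})

#' Mean optical density per patch
#'
#' Tissue-content score used for background exclusion: the mean OD over all
#' pixels and all three RGB-derived OD channels. White background scores 0.
#'
#' @param patches a \linkS4class{PatchSet}.
#' @return numeric vector, one score per patch.
#' @export
patchMeanOD <- function(patches) {
  vapply(patches@pixels, function(p) mean(odTransform(p)), numeric(1))
}

#' Exclude background patches, optionally keeping the top k by tissue content
#'
#' Drops patches whose mean OD falls below \code{threshold}; survivors are
#' ordered by decreasing mean OD (ties broken by lexicographic patch_id). If
#' \code{keepTopK} is set, exactly that many top patches are returned.
#'
#' @param patches a \linkS4class{PatchSet}.
#' @param threshold mean-OD background cutoff (default 0.15).
#' @param keepTopK optional count of patches to retain.
#' @return a \linkS4class{PatchSet} of surviving patches.
#' @export
filterBackground <- function(patches, threshold = 0.15, keepTopK = NULL) {
  if (length(patches) == 0L)
    stop("empty patch set", call. = FALSE)
  score <- patchMeanOD(patches)
  keep <- which(score >= threshold)
  ord <- keep[order(-score[keep], patches@info$patch_id[keep])]
  if (!is.null(keepTopK)) {
    if (keepTopK > length(ord))
      stop(sprintf(
        "keepTopK = %d exceeds the %d patches surviving the background filter",
        keepTopK, length(ord)), call. = FALSE)
    ord <- ord[seq_len(keepTopK)]
  }
  patches[ord]
}

#' Grouped, stratified train/validation/test split of ROIs
#'
#' Shuffles ROIs within each class with the given seed and assigns
#' \code{round(fraction * n_class)} ROIs per partition, remainders going to
#' train. Splitting is by ROI, so all patches of an ROI share a partition
#' and no patch-level leakage can occur.
#'
#' @param manifest data.frame with columns \code{roi_id} and \code{class}
#'   (one row per ROI; duplicated roi_ids are collapsed).
#' @param fractions named numeric vector \code{c(train=, val=, test=)}
#'   summing to 1 (default 0.64/0.16/0.20).
#' @param seed integer RNG seed.
#' @return the manifest with a \code{partition} factor column
#'   (train/val/test).
#' @examples
#' m <- data.frame(roi_id = sprintf("r%03d", 1:500),
#'                 class = rep(c("benign", "malignant"), each = 250))
#' table(splitRois(m, seed = 1)$partition)  # 320 / 80 / 100
#' @export
splitRois <- function(manifest,
                      fractions = c(train = 0.64, val = 0.16, test = 0.20),
                      seed = 1L) {
  stopifnot(all(c("roi_id", "class") %in% names(manifest)))
  if (any(fractions <= 0) || any(fractions >= 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must lie in (0,1) and sum to 1", call. = FALSE)
  if (anyNA(manifest$class))
    stop("every ROI needs a class label", call. = FALSE)
  rois <- unique(manifest[, c("roi_id", "class")])
  cnt <- table(rois$class)
  if (any(cnt < 3L))
    stop("each class needs at least 3 ROIs to split", call. = FALSE)
  rois$partition <- NA_character_
  set.seed(seed)
  for (cl in names(cnt)) {
    idx <- which(rois$class == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    nVal <- round(fractions[["val"]] * n)
    nTest <- round(fractions[["test"]] * n)
    nTrain <- n - nVal - nTest  # round(train*n) plus any remainder
    part <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
    rois$partition[idx] <- part
  }
  rois$partition <- factor(rois$partition, levels = c("train", "val", "test"))
  out <- merge(manifest[, setdiff(names(manifest), "partition"), drop = FALSE],
               rois, by = c("roi_id", "class"), sort = FALSE)
  out[order(match(out$roi_id, manifest$roi_id)), , drop = FALSE]
}
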