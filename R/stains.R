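#' Construct a stain deconvolution basis
#'
#' Rows are normalized to unit Euclidean norm. If the residual vector is
#' omitted it is completed as the unit cross product of the Hematoxylin and
#' Eosin vectors, giving an orthogonal third channel that absorbs whatever
#' the two stains do not explain.
#'
#' @param h,e,r numeric length-3 OD vectors over (R, G, B) for Hematoxylin,
#'   Eosin and the residual channel; \code{r} defaults to the unit cross
#'   product of \code{h} and \code{e}.
#' @param name character label for the basis.
#' @return a \linkS4class{StainMatrix}.
#' @examples
#' sm <- ruifrokHE()
#' odMatrix(sm)
#' @export
StainMatrix <- function(h, e, r = NULL, name = "custom") {
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  if (is.null(r)) {
    r <- c(h[2] * e[3] - h[3] * e[2],
           h[3] * e[1] - h[1] * e[3],
           h[1] * e[2] - h[2] * e[1])
  }
  r <- r / sqrt(sum(r^2))
  m <- rbind(H = h, E = e, R = r)
  colnames(m) <- c("R", "G", "B")
  new("StainMatrix", od = m, name = name)
}

#' The standard Ruifrok-Johnston H&E basis
#'
#' The de-facto standard Hematoxylin/Eosin OD vectors used by most colour
#' deconvolution implementations: H = (0.650, 0.704, 0.286),
#' E = (0.072, 0.990, 0.105), residual completed by cross product.
#'
#' @return a \linkS4class{StainMatrix}.
#' @export
ruifrokHE <- function() {
  StainMatrix(h = c(0.650, 0.704, 0.286),
              e = c(0.072, 0.990, 0.105),
              name = "ruifrok-johnston")
}

#' @rdname StainMatrix-class
#' @export
setMethod("odMatrix", "StainMatrix", function(x) x@od)

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix '", object@name, "' (rows: unit OD vectors over R,G,B)\n",
      sep = "")
  print(round(object@od, 4))
})

#' Beer-Lambert optical density transform
#'
#' Converts 8-bit RGB intensities to optical density per channel:
#' \code{OD = -ln(max(v, 1) / 255)}. The floor guard at 1 avoids log(0) for
#' black pixels and keeps OD exactly 0 for pure white, so OD is always
#' nonnegative and the transform inverts \code{v = round(255 * exp(-OD))}
#' up to 8-bit rounding.
#'
#' @param pixels numeric array of 8-bit intensities (any shape; typically
#'   64x64x3).
#' @return array of the same shape with nonnegative OD values; a black pixel
#'   maps to \code{log(255)} (about 5.54).
#' @export
odTransform <- function(pixels) {
  -log(pmax(pixels, 1) / 255)
}

#' Forward Beer-Lambert synthesis from stain concentration fields
#'
#' Renders an 8-bit RGB image from per-pixel Hematoxylin/Eosin concentration
#' maps: \code{OD_c = cH * vH_c + cE * vE_c} per RGB channel c, then
#' \code{I_c = round(255 * exp(-OD_c))} clipped to [0, 255]. This is the
#' exact inverse model that [deconvolveStains()] solves, which makes
#' noise-free synthesis a round-trip oracle for the deconvolution.
#'
#' @param hMap,eMap equal-sized nonnegative matrices of stain concentrations
#'   (dimensionless OD multipliers).
#' @param stainMatrix a \linkS4class{StainMatrix}; default [ruifrokHE()].
#' @return integer array height x width x 3 in [0, 255].
#' @export
beerLambertForward <- function(hMap, eMap, stainMatrix = ruifrokHE()) {
  stopifnot(identical(dim(hMap), dim(eMap)))
  m <- odMatrix(stainMatrix)
  out <- array(0L, dim = c(dim(hMap), 3L))
  for (ch in 1:3) {
    od <- hMap * m["H", ch] + eMap * m["E", ch]
    out[, , ch] <- pmin(255L, pmax(0L, as.integer(round(255 * exp(-od)))))
  }
  storage.mode(out) <- "integer"
  out
}

#' Separate a patch into Hematoxylin and Eosin concentration channels
#'
#' Applies the Beer-Lambert OD transform and inverts the stain mixing model:
#' per pixel, \code{concentrations = OD %*% solve(odMatrix)}. Negative
#' concentrations (quantization/noise artifacts) are clamped to 0. Each
#' channel is also returned quantized to 8 bits over a fixed global range
#' (default [0, 3] OD units) so that histogram features remain comparable
#' across patches.
#'
#' @param pixels 8-bit RGB array (H x W x 3), e.g. from [patchPixels()].
#' @param stainMatrix a \linkS4class{StainMatrix}.
#' @param quantRange length-2 numeric; global concentration range mapped to
#'   [0, 255] for the quantized maps.
#' @return list with elements \code{h}, \code{e} (numeric concentration
#'   matrices, >= 0), \code{h_quant}, \code{e_quant} (integer matrices in
#'   [0, 255]).
#' @examples
#' img <- beerLambertForward(matrix(1, 8, 8), matrix(0, 8, 8))
#' dec <- deconvolveStains(img)
#' range(dec$h)  # ~1 within 8-bit quantization
#' @export
deconvolveStains <- function(pixels, stainMatrix = ruifrokHE(),
                             quantRange = c(0, 3)) {
  m <- odMatrix(stainMatrix)
  inv <- tryCatch(solve(m), error = function(err)
    stop("stain matrix is singular and cannot be inverted", call. = FALSE))
  d <- dim(pixels)
  od <- matrix(odTransform(pixels), ncol = 3L)  # pixels x (R,G,B)
  conc <- od %*% inv                            # pixels x (H,E,R)
  conc[conc < 0] <- 0
  h <- matrix(conc[, 1], d[1], d[2])
  e <- matrix(conc[, 2], d[1], d[2])
  list(h = h, e = e,
       h_quant = quantizeChannel(h, quantRange),
       e_quant = quantizeChannel(e, quantRange))
}

#' Quantize a concentration map to 8-bit gray levels
#'
#' Linear mapping of a fixed global concentration range to [0, 255] with
#' clipping; per-patch min-max scaling is deliberately not used, since it
#' would destroy cross-patch comparability of histogram features.
#'
#' @param values numeric matrix of concentrations.
#' @param range length-2 numeric global range (default [0, 3] OD units).
#' @return integer matrix in [0, 255].
#' @export
quantizeChannel <- function(values, range = c(0, 3)) {
  stopifnot(length(range) == 2L, range[2] > range[1])
  q <- round(255 * (values - range[1]) / (range[2] - range[1]))
  q <- pmin(pmax(q, 0), 255)
  storage.mode(q) <- "integer"
  q
}
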