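#' Parameters for the synthetic H&E tissue generator
#'
#' Returns the generator settings for one tissue class, starting from
#' class-specific defaults that emulate the qualitative morphology of
#' prostate tissue: benign tissue has small, uniform, well-separated glands
#' with abundant stroma; malignant tissue has irregular, crowded masses of
#' neoplastic glands and nucleus-like clutter in the stroma; grade3 and
#' grade5 interpolate/extremize that recipe (grade5 approaches sheets of
#' cells with almost no lumina).
#'
#' @param class_label one of "benign", "malignant", "grade3", "grade5".
#' @param image_size square image edge in pixels; must be divisible by 64.
#' @param gland_radius_mean,gland_radius_sd gland semi-axis distribution
#'   (pixels).
#' @param gland_density glands per 1e4 square pixels.
#' @param nuclear_clutter fraction in [0,1] of stroma covered by
#'   nucleus-like hematoxylin specks.
#' @param h_concentration_range,e_concentration_range length-2 nonnegative
#'   concentration ranges (dimensionless OD multipliers) for the
#'   Hematoxylin and Eosin fields.
#' @param lumen_prob probability that a gland has an open (near-white)
#'   lumen.
#' @param noise_sd additive Gaussian noise sd applied in concentration (OD)
#'   space after the ground truth is recorded.
#' @param seed integer seed; identical (params, seed) gives byte-identical
#'   output.
#' @return a named list of validated parameters (class "synthParams").
#' @export
synthParams <- function(class_label = c("benign", "malignant", "grade3",
                                        "grade5"),
                        image_size = 256L,
                        gland_radius_mean = NULL, gland_radius_sd = NULL,
                        gland_density = NULL, nuclear_clutter = NULL,
                        h_concentration_range = NULL,
                        e_concentration_range = NULL,
                        lumen_prob = NULL, noise_sd = 0.02, seed = 1L) {
  class_label <- match.arg(class_label)
  def <- switch(class_label,
    benign    = list(rm = 8,  rs = 1.2, dens = 1.5, clut = 0.02,
                     h = c(0.25, 0.75), e = c(0.35, 1.00), lum = 1.0),
    grade3    = list(rm = 10, rs = 2.5, dens = 2.5, clut = 0.10,
                     h = c(0.35, 1.00), e = c(0.30, 0.95), lum = 0.8),
    malignant = list(rm = 13, rs = 5.0, dens = 3.5, clut = 0.25,
                     h = c(0.45, 1.20), e = c(0.25, 0.90), lum = 0.4),
    grade5    = list(rm = 16, rs = 7.0, dens = 4.5, clut = 0.35,
                     h = c(0.55, 1.20), e = c(0.20, 0.85), lum = 0.1))
  p <- list(class_label = class_label,
            image_size = as.integer(image_size),
            gland_radius_mean = gland_radius_mean %||% def$rm,
            gland_radius_sd = gland_radius_sd %||% def$rs,
            gland_density = gland_density %||% def$dens,
            nuclear_clutter = nuclear_clutter %||% def$clut,
            h_concentration_range = h_concentration_range %||% def$h,
            e_concentration_range = e_concentration_range %||% def$e,
            lumen_prob = lumen_prob %||% def$lum,
            noise_sd = noise_sd, seed = as.integer(seed))
  if (p$image_size %% 64L != 0L)
    stop("image_size must be divisible by the 64-pixel patch size",
         call. = FALSE)
  rng <- c(p$h_concentration_range, p$e_concentration_range,
           p$gland_radius_mean, p$gland_radius_sd, p$gland_density,
           p$nuclear_clutter, p$noise_sd)
  if (any(rng < 0)) stop("ranges and rates must be nonnegative", call. = FALSE)
  if (p$nuclear_clutter > 1)
    stop("nuclear_clutter must lie in [0, 1]", call. = FALSE)
  class(p) <- "synthParams"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bilinear upsample of a coarse grid to n x n (deterministic smooth field)
smoothField <- function(coarse, n) {
  k <- nrow(coarse)
  pos <- seq(1, k, length.out = n)
  i0 <- pmin(floor(pos), k - 1L); w <- pos - i0
  a <- coarse[i0, , drop = FALSE] * (1 - w) + coarse[i0 + 1L, , drop = FALSE] * w
  b <- a[, i0, drop = FALSE] * rep(1 - w, each = n) +
       a[, i0 + 1L, drop = FALSE] * rep(w, each = n)
  b
}

# pixel index sets of concentric elliptical rings (rotated); returned as a
# list of index matrices so the caller can assign into its maps in place
ellipseRings <- function(n, cx, cy, a, b, theta, fracs) {
  r <- max(a, b)
  xs <- max(1L, floor(cx - r)):min(n, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(n, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(rep(list(NULL), length(fracs)))
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rad <- sqrt(u^2 + v^2)
  rows <- rep(xs, times = length(ys))
  cols <- rep(ys, each = length(xs))
  lapply(fracs, function(fr) {
    m <- rad >= fr[1] & rad < fr[2]
    if (any(m)) cbind(rows[m], cols[m]) else NULL
  })
}

#' Generate one synthetic H&E tissue image with known stain concentrations
#'
#' Draws per-pixel Hematoxylin/Eosin concentration fields from the class
#' recipe (smooth eosin-rich stroma, elliptical glands with
#' hematoxylin-dense epithelium and optional near-white lumina,
#' nucleus-like hematoxylin specks), records them as ground truth, adds
#' Gaussian noise in concentration space, and renders the 8-bit RGB image
#' through the Beer-Lambert forward model. Because the noise is added in OD
#' space, deconvolving a \code{noise_sd = 0} image with the same stain
#' matrix recovers the ground-truth fields up to 8-bit quantization.
#'
#' @param params a [synthParams()] list.
#' @param stainMatrix the \linkS4class{StainMatrix} used for rendering.
#' @return list with \code{image} (integer H x W x 3 array),
#'   \code{truth} (list \code{h_map}, \code{e_map}: the pre-noise
#'   concentration fields) and \code{params}.
#' @examples
#' g <- generateImage(synthParams("benign", image_size = 64, seed = 7))
#' dim(g$image)
#' @export
generateImage <- function(params, stainMatrix = ruifrokHE()) {
  stopifnot(inherits(params, "synthParams"))
  n <- params$image_size
  set.seed(params$seed)
  hr <- params$h_concentration_range
  er <- params$e_concentration_range

  # stroma: eosin-rich smooth field, faint hematoxylin haze
  coarse <- matrix(runif((n %/% 16 + 2)^2), n %/% 16 + 2)
  eMap <- er[1] + (er[2] - er[1]) * (0.45 + 0.35 * smoothField(coarse, n))
  coarse2 <- matrix(runif((n %/% 16 + 2)^2), n %/% 16 + 2)
  hMap <- hr[1] + (hr[2] - hr[1]) * 0.15 * smoothField(coarse2, n)

  # glands: epithelial ring (H-dense), optional lumen (near-white)
  nGlands <- max(1L, as.integer(round(params$gland_density * n^2 / 1e4)))
  for (g in seq_len(nGlands)) {
    cx <- runif(1, 1, n); cy <- runif(1, 1, n)
    a <- max(3, rnorm(1, params$gland_radius_mean, params$gland_radius_sd))
    b <- a * runif(1, 0.55, 1)
    theta <- runif(1, 0, pi)
    hEpi <- runif(1, hr[1] + 0.6 * (hr[2] - hr[1]), hr[2])
    eEpi <- runif(1, er[1], er[1] + 0.4 * (er[2] - er[1]))
    hasLumen <- runif(1) < params$lumen_prob
    if (hasLumen) {
      rg <- ellipseRings(n, cx, cy, a, b, theta,
                         list(c(0, 0.55), c(0.55, 1)))
      # near-white lumen, bounded by the configured concentration ranges
      if (!is.null(rg[[1]])) {
        hMap[rg[[1]]] <- min(0.02, hr[2])
        eMap[rg[[1]]] <- min(0.04, er[2])
      }
      if (!is.null(rg[[2]])) { hMap[rg[[2]]] <- hEpi; eMap[rg[[2]]] <- eEpi }
    } else {
      rg <- ellipseRings(n, cx, cy, a, b, theta, list(c(0, 1)))
      if (!is.null(rg[[1]])) { hMap[rg[[1]]] <- hEpi; eMap[rg[[1]]] <- eEpi }
    }
  }

  # nucleus-like specks in the stroma (drawn in one vectorized pass)
  if (params$nuclear_clutter > 0) {
    speckR <- 1.6
    nSpecks <- as.integer(round(params$nuclear_clutter * n^2 /
                                  (pi * speckR^2)))
    if (nSpecks > 0L) {
      cx <- round(runif(nSpecks, 1, n))
      cy <- round(runif(nSpecks, 1, n))
      off <- expand.grid(dx = -2:2, dy = -2:2)
      off <- off[off$dx^2 + off$dy^2 <= speckR^2, ]
      rows <- outer(cx, off$dx, "+")
      cols <- outer(cy, off$dy, "+")
      ok <- rows >= 1 & rows <= n & cols >= 1 & cols <= n
      idx <- cbind(rows[ok], cols[ok])
      hMap[idx] <- hr[2]
      eMap[idx] <- er[1] * 0.5
    }
  }

  truth <- list(h_map = hMap, e_map = eMap)
  if (params$noise_sd > 0) {
    hMap <- matrix(pmax(0, hMap + rnorm(n * n, 0, params$noise_sd)), n, n)
    eMap <- matrix(pmax(0, eMap + rnorm(n * n, 0, params$noise_sd)), n, n)
  }
  list(image = beerLambertForward(hMap, eMap, stainMatrix),
       truth = truth, params = params)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes \code{nPerClass} PNG images per class plus a CSV manifest with
#' header \code{image_path,roi_id,class}. Per-image seeds are derived from
#' the master seed by a running counter, so the whole dataset is
#' reproducible from (classes, nPerClass, seed).
#'
#' @param outputDir directory to create/write into.
#' @param nPerClass images per class (>= 1).
#' @param classes character vector of class labels understood by
#'   [synthParams()].
#' @param paramsByClass optional named list of [synthParams()] overrides per
#'   class (their \code{seed} fields are replaced by the derived seeds).
#' @param seed master integer seed.
#' @param imageSize edge length of the generated square images.
#' @param stainMatrix the rendering \linkS4class{StainMatrix}.
#' @return the manifest data.frame (invisibly written to
#'   \code{outputDir/manifest.csv}); \code{image_path} is relative to
#'   \code{outputDir}.
#' @export
generateDataset <- function(outputDir, nPerClass,
                            classes = c("benign", "malignant"),
                            paramsByClass = list(), seed = 1L,
                            imageSize = 256L, stainMatrix = ruifrokHE()) {
  stopifnot(nPerClass >= 1L)
  if (!dir.exists(outputDir) &&
      !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outputDir, call. = FALSE)
  rows <- vector("list", length(classes) * nPerClass)
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      p <- paramsByClass[[cl]] %||% synthParams(cl, image_size = imageSize)
      p$seed <- as.integer(seed + k)
      gen <- generateImage(p, stainMatrix)
      roi <- sprintf("%s_%04d", cl, i)
      rel <- file.path("images", paste0(roi, ".png"))
      dir.create(file.path(outputDir, "images"), showWarnings = FALSE)
      writeTissueImage(gen$image, file.path(outputDir, rel))
      rows[[k]] <- data.frame(image_path = rel, roi_id = roi, class = cl,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outputDir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  manifest
}
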