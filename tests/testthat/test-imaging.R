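test_that("gamma correction follows the power law with fixed points", {
  img <- gradientImage(64, 64)
  expect_identical(gammaCorrect(img, 1), img)
  expect_equal(gammaCorrect(array(0L, c(2, 2, 3)), 2.7)[1], 0L)
  expect_equal(gammaCorrect(array(255L, c(2, 2, 3)), 0.3)[1], 255L)
  # round(255 * (64/255)^0.5) = 128
  expect_equal(gammaCorrect(array(64L, c(1, 1, 3)), 0.5)[1], 128L)
  expect_error(gammaCorrect(img, 0), "positive")
  expect_error(gammaCorrect(img, -1), "positive")
})

test_that("gamma correction is monotone non-decreasing in input value", {
  v <- array(0:255, dim = c(256, 1, 1))
  for (g in c(0.25, 0.5, 1, 2.2, 5)) {
    out <- gammaCorrect(v, g)
    expect_true(all(diff(as.vector(out)) >= 0))
    expect_true(all(out >= 0L & out <= 255L))
  }
})

test_that("resize hits the target, preserves constants, and validates input", {
  const <- array(137L, c(256, 256, 3))
  out <- resizeImage(const, 128)
  expect_identical(dim(out), c(128L, 128L, 3L))
  expect_true(all(out == 137L))
  img <- gradientImage(128, 128)
  expect_identical(resizeImage(img, 128), img)  # no-op at current size
  big <- resizeImage(gradientImage(320, 320), 256)
  expect_identical(dim(big), c(256L, 256L, 3L))
  expect_error(resizeImage(img, 100), "divisible")
})

test_that("patch tiling counts and lossless reassembly", {
  g <- generateImage(synthParams("benign", seed = 8))
  ps <- extractPatches(g$image, "roi1", "benign")
  expect_equal(length(ps), 16L)
  info <- patchInfo(ps)
  expect_true(all(info$row0 %% 64 == 0 & info$col0 %% 64 == 0))
  # row-major order
  expect_equal(info$row0[1:4], rep(0L, 4))
  expect_equal(info$col0[1:4], c(0L, 64L, 128L, 192L))
  # reassembly reproduces the image exactly
  rec <- array(0L, dim(g$image))
  for (i in seq_len(length(ps))) {
    r0 <- info$row0[i]; c0 <- info$col0[i]
    rec[(r0 + 1):(r0 + 64), (c0 + 1):(c0 + 64), ] <- patchPixels(ps, i)
  }
  expect_identical(rec, g$image)
  # single-patch edge and remainder-discarding
  one <- extractPatches(g$image[1:64, 1:64, , drop = FALSE], "r")
  expect_equal(length(one), 1L)
  expect_identical(patchPixels(one, 1), g$image[1:64, 1:64, , drop = FALSE])
  odd <- extractPatches(g$image[1:200, 1:140, , drop = FALSE], "r")
  expect_equal(length(odd), 3L * 2L)
  expect_error(extractPatches(g$image[1:32, 1:32, , drop = FALSE], "r"),
               "smaller")
})

test_that("background filtering drops white patches and honors keepTopK", {
  white <- array(255L, c(64, 64, 3))
  tissue <- beerLambertForward(matrix(0.8, 64, 64), matrix(0.6, 64, 64))
  img <- rbind2x2 <- array(0L, c(128, 128, 3))
  img[1:64, 1:64, ] <- white
  img[1:64, 65:128, ] <- tissue
  img[65:128, 1:64, ] <- tissue
  img[65:128, 65:128, ] <- white
  ps <- extractPatches(img, "roi")
  kept <- filterBackground(ps, threshold = 0.15)
  expect_equal(length(kept), 2L)
  expect_true(all(patchMeanOD(kept) > 0.15))
  # keepTopK exact count and over-request error
  expect_equal(length(filterBackground(ps, threshold = 0.15, keepTopK = 1)),
               1L)
  expect_error(filterBackground(ps, threshold = 0.15, keepTopK = 3),
               "exceeds")
  # threshold 0 keeps everything (all-tissue case unchanged)
  allTissue <- extractPatches(tissue, "t")
  expect_equal(length(filterBackground(allTissue, threshold = 0)), 1L)
})

test_that("ROI splitting reproduces the 320/80/100 layout and partitions", {
  m <- data.frame(roi_id = sprintf("r%03d", 1:500),
                  class = rep(c("benign", "malignant"), each = 250))
  sp <- splitRois(m, seed = 7)
  expect_equal(as.integer(table(sp$partition)), c(320L, 80L, 100L))
  # stratified: each class contributes exactly half of each partition
  expect_equal(as.integer(table(sp$partition, sp$class)[, "benign"]),
               c(160L, 40L, 50L))
  # determinism and partition laws
  sp2 <- splitRois(m, seed = 7)
  expect_identical(sp$partition, sp2$partition)
  expect_false(identical(sp$partition, splitRois(m, seed = 8)$partition))
  expect_true(all(!is.na(sp$partition)))
  expect_equal(sort(sp$roi_id), sort(m$roi_id))
  # 50 ROIs -> 32/8/10
  m50 <- data.frame(roi_id = sprintf("q%02d", 1:50),
                    class = rep(c("a", "b"), each = 25))
  expect_equal(as.integer(table(splitRois(m50, seed = 1)$partition)),
               c(32L, 8L, 10L))
  # every patch of an ROI inherits its partition: splitting is ROI-level
  expect_error(splitRois(data.frame(roi_id = c("a", "b"),
                                    class = c("x", "y")), seed = 1),
               "at least 3")
  expect_error(splitRois(m, fractions = c(train = 0.5, val = 0.2,
                                          test = 0.2), seed = 1),
               "sum to 1")
})

test_that("PNG image I/O round-trips 8-bit pixels", {
  img <- gradientImage(64, 64)
  path <- tempfile(fileext = ".png")
  writeTissueImage(img, path)
  back <- readTissueImage(path)
  expect_identical(back, img)
})
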