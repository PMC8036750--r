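test_that("constant patches give the degenerate FOS vector", {
  f <- computeFOS(matrix(7, 64, 64))
  expect_equal(unname(f["energy"]), 64 * 64 * 49)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 0)
})

test_that("the two-level worked example evaluates exactly", {
  f <- computeFOS(c(0, 0, 255, 255))
  expect_equal(unname(f["entropy"]), 1.0)
  expect_equal(unname(f["uniformity"]), 0.5)
  expect_equal(unname(f["variance"]), 16256.25)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 1.0)
  expect_equal(unname(f["energy"]), 130050)
})

test_that("FOS features ignore spatial arrangement", {
  set.seed(4)
  x <- matrix(sample(0:255, 4096, replace = TRUE), 64)
  mirrored <- x[, 64:1]
  shuffled <- matrix(sample(as.vector(x)), 64)
  expect_equal(computeFOS(x), computeFOS(mirrored), tolerance = 1e-12)
  expect_equal(computeFOS(x), computeFOS(shuffled), tolerance = 1e-12)
})

test_that("features match the explicit-loop oracle to 1e-9 relative", {
  set.seed(12)
  for (i in 1:100) {
    x <- switch(1 + i %% 4,
      sample(0:255, 64, replace = TRUE),
      rep(sample(0:255, 1), 32),
      round(runif(128, 0, 255)),
      sample(0:7, 256, replace = TRUE))
    expect_equal(computeFOS(x), bruteFOS(x), tolerance = 1e-9)
  }
})

test_that("variance and energy scale quadratically with contrast", {
  set.seed(5)
  x <- sample(0:100, 256, replace = TRUE)
  f1 <- computeFOS(x)
  f2 <- computeFOS(2 * x)  # no clipping below 256 bins
  expect_equal(unname(f2["variance"]), unname(4 * f1["variance"]))
  expect_equal(unname(f2["energy"]), unname(4 * f1["energy"]))
  expect_error(computeFOS(numeric(0)), "empty")
})

test_that("feature table standardizes on train only, with degenerate guard", {
  set.seed(6)
  n <- 30
  rec <- data.frame(patch_id = sprintf("p%02d", 1:n),
                    roi_id = rep(sprintf("r%02d", 1:10), each = 3),
                    class_label = rep(c("benign", "malignant"),
                                      length.out = n),
                    partition = factor(rep(c("train", "val", "test"),
                                           times = c(18, 6, 6)),
                                       levels = c("train", "val", "test")))
  for (col in c(paste0("h_", c("energy", "entropy", "kurtosis", "skewness",
                               "variance", "uniformity")),
                paste0("e_", c("energy", "entropy", "kurtosis", "skewness",
                               "variance", "uniformity"))))
    rec[[col]] <- rnorm(n, 10, 3)
  rec$h_energy <- rec$h_energy + 100  # shifted column
  fe <- buildFeatureTable(rec)
  sc <- SummarizedExperiment::assay(fe, "scaled")
  tr <- sc[, fe$partition == "train"]
  expect_lt(max(abs(rowMeans(tr))), 1e-9)
  expect_lt(max(abs(apply(tr, 1, sd) - 1)), 1e-9)
  # constant column -> left at 0, never divided by zero
  rec2 <- rec
  rec2$e_uniformity <- 5
  fe2 <- buildFeatureTable(rec2)
  expect_true(all(SummarizedExperiment::assay(fe2,
                                              "scaled")["e_uniformity", ]
                  == 0))
  # missing train partition errors
  rec3 <- rec
  rec3$partition <- factor("test", levels = c("train", "val", "test"))
  expect_error(buildFeatureTable(rec3), "train")
})

test_that("feature CSV round-trips at full precision", {
  g <- generateImage(synthParams("benign", seed = 21))
  ps <- extractPatches(g$image, "roiA", "benign")
  rec <- extractDualChannelFeatures(ps)
  rec$partition <- factor("train", levels = c("train", "val", "test"))
  fe <- buildFeatureTable(rec)
  path <- tempfile(fileext = ".csv")
  writeFeatureCSV(fe, path)
  fe2 <- readFeatureCSV(path)
  expect_equal(SummarizedExperiment::assay(fe, "raw"),
               SummarizedExperiment::assay(fe2, "raw"),
               tolerance = 1e-12)
  expect_identical(fe$patch_id, fe2$patch_id)
  expect_equal(nrow(fe), 12L)
  expect_equal(ncol(fe2), 16L)
})
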