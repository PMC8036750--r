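test_that("one-way ANOVA decomposition matches hand computation", {
  res <- anovaEffect(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(res$ss_effect, 13.5)
  expect_equal(res$ss_total, 17.5)
  expect_equal(res$eta_squared, 13.5 / 17.5)
  expect_equal(res$f_value, 13.5)
  # identical groups: no between-group variance
  same <- anovaEffect(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(same$ss_effect, 0)
  expect_equal(same$eta_squared, 0)
  expect_equal(same$f_value, 0)
  # zero within-group variance, different means: all variance between
  sep <- anovaEffect(c(1, 1, 1, 5, 5, 5), rep(c("A", "B"), each = 3))
  expect_equal(sep$eta_squared, 1)
  expect_equal(sep$p_value, 0)
  expect_error(anovaEffect(1:3, c("A", "A", "B")), "at least 2")
})

test_that("F equals t-squared for two groups and eta2 matches brute force", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    v <- c(rnorm(n1), rnorm(n2, mean = runif(1, -1, 1)))
    gr <- rep(c("A", "B"), c(n1, n2))
    res <- anovaEffect(v, gr)
    tt <- t.test(v ~ gr, var.equal = TRUE)
    expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
    expect_equal(res$eta_squared, bruteEtaSquared(v, gr), tolerance = 1e-9)
    # cross-check against stats::aov on the same data
    av <- summary(aov(v ~ factor(gr)))[[1]]
    expect_equal(res$ss_effect, av[["Sum Sq"]][1], tolerance = 1e-9)
  }
})

test_that("effect size categories respect the 0.01/0.06/0.14 thresholds", {
  # construct two-group data with a target eta squared analytically:
  # equal groups, means +/- d, within-sd fixed => eta2 = d^2/(d^2 + s2w)
  mk <- function(eta2, n = 2000) {
    s2w <- 1
    d <- sqrt(eta2 * s2w / (1 - eta2))
    base <- rep(c(-1, 1), n / 2) # within-group pattern, variance 1, mean 0
    v <- c(base - d, base + d)
    list(v = v, g = rep(c("A", "B"), each = n))
  }
  for (case in list(c(0.005, NA), c(0.03, NA), c(0.10, NA), c(0.25, NA))) {
    dat <- mk(case[1])
    res <- anovaEffect(dat$v, dat$g)
    expect_equal(res$eta_squared, case[1], tolerance = 1e-9)
    want <- if (case[1] >= 0.14) "large" else if (case[1] >= 0.06) "medium"
            else "small"
    expect_identical(res$effect_category, want)
  }
})

test_that("RFE keeps exactly k families with a valid permutation ranking", {
  pl <- plantedFeatureTable(n = 200, seed = 2)
  rk <- rfeRank(pl$x, pl$y, k = 5, seed = 3)
  expect_setequal(rk$rank, 1:6)
  expect_equal(sum(rk$keep), 5L)
  expect_setequal(rk$feature, c("energy", "entropy", "kurtosis",
                                "skewness", "variance", "uniformity"))
  # single-feature edge
  x1 <- pl$x[, c("h_energy", "e_energy"), drop = FALSE]
  rk1 <- rfeRank(x1, pl$y, k = 1, seed = 1)
  expect_equal(rk1$feature, "energy")
  expect_true(rk1$keep)
  # guardrails
  expect_error(rfeRank(pl$x, pl$y, k = 7), "exceeds")
  expect_error(rfeRank(pl$x, rep("a", 200), k = 5), "single class")
})

test_that("a planted pure-noise family is eliminated first in >=90% of runs", {
  hits <- 0L
  for (s in 1:100) {
    pl <- plantedFeatureTable(n = 240, seed = 1000 + s)
    rk <- rfeRank(pl$x, pl$y, k = 5, seed = s)
    if (!rk$keep[rk$feature == "uniformity"]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("two-step selection intersects RFE with the ANOVA filter", {
  pl <- plantedFeatureTable(n = 300, seed = 9, delta = 1.5)
  sel <- selectFeatures(pl$x, pl$y, k = 5, seed = 4)
  expect_length(sel$kept, 5L)
  expect_length(sel$columns, 10L)  # both channels of each kept family
  expect_true(all(sel$report$p_value < 0.05))
  expect_true(all(c("f_value", "eta_squared", "effect_category")
                  %in% names(sel$report)))
  # a perfectly separating feature is kept with eta2 near 1
  set.seed(8)
  y <- rep(c("benign", "malignant"), each = 50)
  x <- cbind(sep = c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1)),
             junk = rnorm(100))
  sel2 <- selectFeatures(x, y, k = 1, seed = 1)
  expect_identical(sel2$kept, "sep")
  expect_gt(sel2$report$eta_squared, 0.99)
  # all-noise features fail the filter loudly rather than guessing
  set.seed(10)
  xn <- matrix(rnorm(600), 100)
  colnames(xn) <- paste0("n", 1:6)
  yn <- rep(c("a", "b"), each = 50)
  expect_error(suppressWarnings(selectFeatures(xn, yn, k = 1, alpha = 1e-9,
                                               seed = 2)),
               "ANOVA filter")
})
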