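sepData <- function(n = 120, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n)
  colnames(x) <- c("f1", "f2")
  y <- ifelse(x[, 1] > 0, "malignant", "benign")
  x[, 1] <- x[, 1] + ifelse(y == "malignant", 2, -2)  # wide margin
  list(x = x, y = y)
}

test_that("all classical kinds fit a separable problem perfectly", {
  d <- sepData()
  for (kind in c("svm", "lr", "bagging", "boosting")) {
    m <- trainClassifier(d$x, d$y, kind, seed = 5)
    pr <- predictScores(m, d$x)
    expect_identical(pr$label, d$y)
    expect_true(all(pr$score >= 0 & pr$score <= 1))
    # duplicated rows score identically; reruns are deterministic
    dup <- predictScores(m, d$x[c(1, 1, 2, 2), ])
    expect_identical(dup$score[1], dup$score[2])
    m2 <- trainClassifier(d$x, d$y, kind, seed = 5)
    expect_equal(predictScores(m2, d$x)$score, pr$score)
  }
  expect_error(trainClassifier(d$x, rep("one", nrow(d$x)), "svm"),
               "single class")
})

test_that("positive class is malignant (or grade5) by convention", {
  d <- sepData()
  m <- trainClassifier(d$x, d$y, "boosting", seed = 1)
  expect_identical(m@positiveClass, "malignant")
  yg <- ifelse(d$y == "malignant", "grade5", "grade3")
  mg <- trainClassifier(d$x, yg, "boosting", seed = 1)
  expect_identical(mg@positiveClass, "grade5")
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(20)
  n <- 240
  x <- matrix(rnorm(n * 6), n)
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c("benign", "malignant"), each = n / 2)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    yp <- sample(y)
    tr <- sample.int(n, n * 2 / 3)
    m <- trainClassifier(x[tr, ], yp[tr], "lr", seed = s)
    pr <- predictScores(m, x[-tr, ])
    mean(pr$label == yp[-tr])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("DC-BiLSTM outputs 0.5 before any training step", {
  d <- sepData(60)
  m <- trainDCBiLSTM(d$x, d$x, d$y, config = list(epochs = 0L, hidden = 8L),
                     seed = 1)
  pr <- predictScores(m, list(h = d$x, e = d$x))
  expect_equal(pr$score, rep(0.5, 60))
})

test_that("DC-BiLSTM learns a separable dual-channel problem", {
  set.seed(44)
  n <- 300
  h <- matrix(rnorm(n * 5), n); e <- matrix(rnorm(n * 5), n)
  y <- rep(c("benign", "malignant"), length.out = n)
  h[y == "malignant", ] <- h[y == "malignant", ] + 1.5
  e[y == "malignant", ] <- e[y == "malignant", ] + 1.5
  tr <- seq_len(200); te <- 201:300
  cfgB <- list(epochs = 30L, hidden = 16L, patience = 30L)
  m <- trainDCBiLSTM(h[tr, ], e[tr, ], y[tr], config = cfgB, seed = 2)
  acc <- mean(predictScores(m, list(h = h[te, ], e = e[te, ]))$label
              == y[te])
  expect_gte(acc, 0.9)
  # determinism of fit and scoring
  m2 <- trainDCBiLSTM(h[tr, ], e[tr, ], y[tr], config = cfgB, seed = 2)
  expect_equal(predictScores(m, list(h = h[te, ], e = e[te, ]))$score,
               predictScores(m2, list(h = h[te, ], e = e[te, ]))$score)
  # architecture symmetry: swapping channels consistently changes little
  ms <- trainDCBiLSTM(e[tr, ], h[tr, ], y[tr], config = cfgB, seed = 2)
  accS <- mean(predictScores(ms, list(h = e[te, ], e = h[te, ]))$label
               == y[te])
  expect_lte(abs(acc - accS), 0.05)
  # mismatched channel counts are rejected
  expect_error(trainDCBiLSTM(h[1:10, ], e[1:9, ], y[1:10]), "differ")
})

test_that("scoring validates feature dimensions and handles empty input", {
  d <- sepData()
  m <- trainClassifier(d$x, d$y, "boosting", seed = 2)
  expect_error(predictScores(m, d$x[, 1, drop = FALSE]), "feature")
  empty <- predictScores(m, d$x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})
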