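# Independent brute-force oracles, deliberately written with explicit loops
# so they share no code path with the package implementations.

bruteFOS <- function(values, nbins = 256L) {
  x <- as.numeric(values)
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v / n
  m2 <- m3 <- m4 <- energy <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2 / n
    m3 <- m3 + d^3 / n
    m4 <- m4 + d^4 / n
    energy <- energy + v^2
  }
  counts <- rep(0, nbins)
  for (v in x) {
    b <- min(nbins - 1, max(0, floor(v))) + 1
    counts[b] <- counts[b] + 1
  }
  entropy <- 0
  uniformity <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / n
      entropy <- entropy - p * log2(p)
      uniformity <- uniformity + p^2
    }
  }
  c(energy = energy, entropy = entropy,
    kurtosis = if (m2 == 0) 0 else m4 / m2^2,
    skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    variance = m2, uniformity = uniformity)
}

bruteEtaSquared <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- 0
  for (g in unique(groups)) {
    vg <- values[groups == g]
    ssb <- ssb + length(vg) * (mean(vg) - grand)^2
  }
  sst <- 0
  for (v in values) sst <- sst + (v - grand)^2
  ssb / sst
}

# pairwise-comparison AUC estimator: P(score_pos > score_neg), ties 1/2
bruteAUC <- function(truth, scores, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small dual-channel feature table with planted class signal: families
# named after the FOS set; `noise` carries no signal in either channel
plantedFeatureTable <- function(n = 300L, seed = 1L,
                                informative = c("energy", "entropy",
                                                "kurtosis", "skewness",
                                                "variance"),
                                noiseFamily = "uniformity",
                                delta = 1.0) {
  set.seed(seed)
  y <- rep(c("benign", "malignant"), length.out = n)
  fams <- c(informative, noiseFamily)
  x <- matrix(rnorm(n * 2 * length(fams)), n)
  colnames(x) <- c(paste0("h_", fams), paste0("e_", fams))
  shift <- (y == "malignant") * delta
  for (f in informative) {
    x[, paste0("h_", f)] <- x[, paste0("h_", f)] + shift
    x[, paste0("e_", f)] <- x[, paste0("e_", f)] + shift
  }
  list(x = x, y = y)
}

# tiny deterministic RGB test image: smooth gradient plus blocks
gradientImage <- function(h = 128L, w = 128L) {
  r <- matrix(rep(seq(0L, 255L, length.out = h), w), h, w)
  g <- t(matrix(rep(seq(0L, 255L, length.out = w), h), w, h))
  b <- (r + g) / 2
  out <- array(0L, c(h, w, 3L))
  out[, , 1] <- as.integer(round(r))
  out[, , 2] <- as.integer(round(g))
  out[, , 3] <- as.integer(round(b))
  out
}
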