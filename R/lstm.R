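# Minimal LSTM engine for the dual-channel bidirectional classifier.
# Parameters per cell: W (Din x 4H), U (H x 4H), b (4H), gate order i,f,o,g.
# All math is batched matrix algebra; sequences are lists of batch x D
# matrices, one per timestep.

sigmoid <- function(x) 1 / (1 + exp(-x))

initCell <- function(din, h) {
  s <- sqrt(6 / (din + 4 * h))
  list(W = matrix(runif(din * 4 * h, -s, s), din, 4 * h),
       U = matrix(runif(h * 4 * h, -sqrt(6 / (5 * h)), sqrt(6 / (5 * h))),
                  h, 4 * h),
       b = {b <- rep(0, 4 * h); b[(h + 1):(2 * h)] <- 1; b})  # forget bias 1
}

cellForward <- function(xs, p, h) {
  Tn <- length(xs); b <- nrow(xs[[1]])
  hPrev <- matrix(0, b, h); cPrev <- matrix(0, b, h)
  hs <- vector("list", Tn); cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- xs[[t]] %*% p$W + hPrev %*% p$U +
      matrix(p$b, b, 4 * h, byrow = TRUE)
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, (h + 1):(2 * h), drop = FALSE])
    o <- sigmoid(z[, (2 * h + 1):(3 * h), drop = FALSE])
    g <- tanh(z[, (3 * h + 1):(4 * h), drop = FALSE])
    cNew <- f * cPrev + i * g
    tc <- tanh(cNew)
    hNew <- o * tc
    cache[[t]] <- list(x = xs[[t]], i = i, f = f, o = o, g = g,
                       cPrev = cPrev, hPrev = hPrev, tc = tc)
    hPrev <- hNew; cPrev <- cNew
    hs[[t]] <- hNew
  }
  list(hs = hs, cache = cache)
}

# dhs: list of batch x H gradients on every timestep output (may be zeros)
cellBackward <- function(p, cache, dhs, h) {
  Tn <- length(cache); b <- nrow(dhs[[1]])
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dhNext <- matrix(0, b, h); dcNext <- matrix(0, b, h)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    dh <- dhs[[t]] + dhNext
    dc <- dcNext + dh * ca$o * (1 - ca$tc^2)
    dzo <- (dh * ca$tc) * ca$o * (1 - ca$o)
    dzi <- (dc * ca$g) * ca$i * (1 - ca$i)
    dzf <- (dc * ca$cPrev) * ca$f * (1 - ca$f)
    dzg <- (dc * ca$i) * (1 - ca$g^2)
    dz <- cbind(dzi, dzf, dzo, dzg)
    dW <- dW + crossprod(ca$x, dz)
    dU <- dU + crossprod(ca$hPrev, dz)
    db <- db + colSums(dz)
    dhNext <- dz %*% t(p$U)
    dcNext <- dc * ca$f
    dxs[[t]] <- dz %*% t(p$W)
  }
  list(dxs = dxs, grads = list(W = dW, U = dU, b = db))
}

# bidirectional layer: forward cell on t = 1..T, backward cell on reversed
# order; output per timestep is cbind(h_fwd[t], h_bwd[t]) (2H columns)
biForward <- function(xs, pf, pb, h) {
  fwd <- cellForward(xs, pf, h)
  bwd <- cellForward(rev(xs), pb, h)
  Tn <- length(xs)
  hs <- lapply(seq_len(Tn), function(t)
    cbind(fwd$hs[[t]], bwd$hs[[Tn - t + 1L]]))
  list(hs = hs, fwd = fwd, bwd = bwd)
}

biBackward <- function(pf, pb, fw, dhs, h) {
  Tn <- length(dhs)
  dhF <- lapply(dhs, function(d) d[, 1:h, drop = FALSE])
  dhB <- lapply(rev(dhs), function(d)
    d[, (h + 1):(2 * h), drop = FALSE])
  bf <- cellBackward(pf, fw$fwd$cache, dhF, h)
  bb <- cellBackward(pb, fw$bwd$cache, dhB, h)
  dxs <- lapply(seq_len(Tn), function(t)
    bf$dxs[[t]] + bb$dxs[[Tn - t + 1L]])
  list(dxs = dxs, gf = bf$grads, gb = bb$grads)
}

# two stacked BiLSTM layers per channel; the head sees the terminal states
# of layer 2 (forward pass at t = T, backward pass at t = 1)
initDCBiLSTM <- function(din, h, seed) {
  set.seed(seed)
  p <- list()
  for (ch in c("h", "e")) {
    p[[paste0(ch, "1f")]] <- initCell(din, h)
    p[[paste0(ch, "1b")]] <- initCell(din, h)
    p[[paste0(ch, "2f")]] <- initCell(2 * h, h)
    p[[paste0(ch, "2b")]] <- initCell(2 * h, h)
  }
  p$out <- list(W = matrix(0, 4 * h, 2), b = rep(0, 2))  # zero logits -> 0.5
  p
}

channelForward <- function(xs, p, ch, h) {
  l1 <- biForward(xs, p[[paste0(ch, "1f")]], p[[paste0(ch, "1b")]], h)
  l2 <- biForward(l1$hs, p[[paste0(ch, "2f")]], p[[paste0(ch, "2b")]], h)
  Tn <- length(xs)
  feat <- cbind(l2$fwd$hs[[Tn]], l2$bwd$hs[[Tn]])  # [h_fwd_T, h_bwd_(t=1)]
  list(feat = feat, l1 = l1, l2 = l2, Tn = Tn)
}

dcForward <- function(hx, ex, p, h) {
  fh <- channelForward(hx, p, "h", h)
  fe <- channelForward(ex, p, "e", h)
  z <- cbind(fh$feat, fe$feat)                      # batch x 4H
  logits <- z %*% p$out$W + matrix(p$out$b, nrow(z), 2, byrow = TRUE)
  m <- apply(logits, 1, max)
  el <- exp(logits - m)
  probs <- el / rowSums(el)
  list(probs = probs, z = z, fh = fh, fe = fe)
}

channelBackward <- function(fw, dfeat, p, ch, h) {
  Tn <- fw$Tn; b <- nrow(dfeat)
  zero <- matrix(0, b, 2 * h)
  # layer-2 output grads: only the terminal fwd/bwd states feed the head
  dhs2 <- rep(list(zero), Tn)
  dhs2[[Tn]] <- dhs2[[Tn]] +
    cbind(dfeat[, 1:h, drop = FALSE], matrix(0, b, h))
  dhs2[[1L]] <- dhs2[[1L]] +
    cbind(matrix(0, b, h), dfeat[, (h + 1):(2 * h), drop = FALSE])
  b2 <- biBackward(p[[paste0(ch, "2f")]], p[[paste0(ch, "2b")]], fw$l2,
                   dhs2, h)
  b1 <- biBackward(p[[paste0(ch, "1f")]], p[[paste0(ch, "1b")]], fw$l1,
                   b2$dxs, h)
  g <- list(); g[[paste0(ch, "2f")]] <- b2$gf; g[[paste0(ch, "2b")]] <- b2$gb
  g[[paste0(ch, "1f")]] <- b1$gf; g[[paste0(ch, "1b")]] <- b1$gb
  g
}

dcBackward <- function(fw, y, p, h) {
  b <- nrow(fw$probs)
  dlogits <- (fw$probs - cbind(1 - y, y)) / b
  g <- list(out = list(W = crossprod(fw$z, dlogits),
                       b = colSums(dlogits)))
  dz <- dlogits %*% t(p$out$W)
  g <- c(g, channelBackward(fw$fh, dz[, 1:(2 * h), drop = FALSE], p, "h", h))
  g <- c(g, channelBackward(fw$fe, dz[, (2 * h + 1):(4 * h), drop = FALSE],
                            p, "e", h))
  g
}

adamInit <- function(p) rapply(p, function(m) m * 0, how = "replace")

adamStep <- function(p, g, m1, m2, t, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(g)) {
    for (s in names(g[[nm]])) {
      gr <- g[[nm]][[s]]
      m1[[nm]][[s]] <- b1 * m1[[nm]][[s]] + (1 - b1) * gr
      m2[[nm]][[s]] <- b2 * m2[[nm]][[s]] + (1 - b2) * gr^2
      mh <- m1[[nm]][[s]] / (1 - b1^t)
      vh <- m2[[nm]][[s]] / (1 - b2^t)
      p[[nm]][[s]] <- p[[nm]][[s]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(p = p, m1 = m1, m2 = m2)
}

# rows of a samples x T (or samples x T x D) input to a timestep list
toSequence <- function(x) {
  if (is.matrix(x)) {
    lapply(seq_len(ncol(x)), function(t) x[, t, drop = FALSE])
  } else if (length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[2]), function(t) {
      xt <- x[, t, , drop = FALSE]
      dim(xt) <- c(dim(x)[1], dim(x)[3])
      xt
    })
  } else stop("sequence input must be a matrix or 3d array", call. = FALSE)
}

subsetSeq <- function(xs, idx) lapply(xs, function(m) m[idx, , drop = FALSE])

dcLoss <- function(probs, y) {
  eps <- 1e-12
  -mean(log(pmax(ifelse(y == 1, probs[, 2], probs[, 1]), eps)))
}
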