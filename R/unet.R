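## U-Net style encoder-decoder for single-target (cell or nucleus) binary
## segmentation. Encoder levels 1..depth-1 are double-conv blocks followed by
## 2x2 max pooling; level `depth` is the bottleneck; the decoder mirrors the
## encoder with nearest-neighbor upsampling, 1x1 channel halving, and skip
## concatenation. A final 1x1 convolution plus sigmoid yields the
## per-pixel foreground probability map. Internal.

unetChannels <- function(depth, base) base * 2L^(seq_len(depth) - 1L)

unetInit <- function(depth, base, cin = 3L) {
  f <- unetChannels(depth, base)
  p <- list()
  for (l in seq_len(depth)) {
    inc <- if (l == 1L) cin else f[l - 1L]
    p[[sprintf("enc%d_c1", l)]] <- nnConvInit(inc, f[l])
    p[[sprintf("enc%d_c2", l)]] <- nnConvInit(f[l], f[l])
  }
  for (l in rev(seq_len(depth - 1L))) {
    p[[sprintf("up%d", l)]] <- nnDenseInit(f[l + 1L], f[l])   # 1x1 projection
    p[[sprintf("dec%d_c1", l)]] <- nnConvInit(2L * f[l], f[l])
    p[[sprintf("dec%d_c2", l)]] <- nnConvInit(f[l], f[l])
  }
  p[["out"]] <- nnDenseInit(f[1L], 1L)
  ## flatten to one named list of arrays for the optimizer
  flat <- list()
  for (nm in names(p)) {
    flat[[paste0(nm, "_W")]] <- p[[nm]]$W
    flat[[paste0(nm, "_b")]] <- p[[nm]]$b
  }
  flat
}

.par <- function(params, nm) list(W = params[[paste0(nm, "_W")]], b = params[[paste0(nm, "_b")]])

unetForward <- function(params, X, depth, keepCache = TRUE) {
  cache <- list()
  skips <- list()
  A <- X
  for (l in seq_len(depth)) {
    c1 <- nnConvFwd(A, .par(params, sprintf("enc%d_c1", l)))
    r1 <- nnReluFwd(c1$out)
    c2 <- nnConvFwd(r1$out, .par(params, sprintf("enc%d_c2", l)))
    r2 <- nnReluFwd(c2$out)
    if (keepCache) cache[[sprintf("enc%d", l)]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2)
    A <- r2$out
    if (l < depth) {
      skips[[l]] <- A
      pl <- nnPoolFwd(A)
      if (keepCache) cache[[sprintf("pool%d", l)]] <- pl
      A <- pl$out
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    up <- nnUpFwd(A)
    pj <- nnConv1Fwd(up, .par(params, sprintf("up%d", l)))
    cc <- nnConcat(skips[[l]], pj$out)
    c1 <- nnConvFwd(cc, .par(params, sprintf("dec%d_c1", l)))
    r1 <- nnReluFwd(c1$out)
    c2 <- nnConvFwd(r1$out, .par(params, sprintf("dec%d_c2", l)))
    r2 <- nnReluFwd(c2$out)
    if (keepCache) cache[[sprintf("dec%d", l)]] <- list(pj = pj, c1 = c1, r1 = r1, c2 = c2, r2 = r2)
    A <- r2$out
  }
  outc <- nnConv1Fwd(A, .par(params, "out"))
  prob <- nnSigmoid(outc$out)
  if (keepCache) cache[["out"]] <- outc
  list(prob = prob, cache = cache)
}

## Backward pass from d(loss)/d(logit); returns gradients named like params
unetBackward <- function(params, dLogit, cache, depth) {
  g <- list()
  store <- function(nm, res) {
    g[[paste0(nm, "_W")]] <<- res$dW
    g[[paste0(nm, "_b")]] <<- res$db
    res$dX
  }
  dA <- store("out", nnConv1Bwd(dLogit, cache[["out"]], .par(params, "out")))
  dSkips <- list()
  for (l in seq_len(depth - 1L)) {
    cc <- cache[[sprintf("dec%d", l)]]
    d2 <- nnReluBwd(dA, cc$r2)
    dA <- store(sprintf("dec%d_c2", l), nnConvBwd(d2, cc$c2, .par(params, sprintf("dec%d_c2", l))))
    d1 <- nnReluBwd(dA, cc$r1)
    dcc <- store(sprintf("dec%d_c1", l), nnConvBwd(d1, cc$c1, .par(params, sprintf("dec%d_c1", l))))
    cSkip <- dim(dcc)[4] %/% 2L
    sp <- nnSplit(dcc, cSkip)
    dSkips[[l]] <- sp$dA
    dUp <- store(sprintf("up%d", l), nnConv1Bwd(sp$dB, cc$pj, .par(params, sprintf("up%d", l))))
    dA <- nnUpBwd(dUp)
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      dA <- nnPoolBwd(dA, cache[[sprintf("pool%d", l)]])
      dA <- dA + dSkips[[l]]
    }
    ec <- cache[[sprintf("enc%d", l)]]
    d2 <- nnReluBwd(dA, ec$r2)
    dA <- store(sprintf("enc%d_c2", l), nnConvBwd(d2, ec$c2, .par(params, sprintf("enc%d_c2", l))))
    d1 <- nnReluBwd(dA, ec$r1)
    dA <- store(sprintf("enc%d_c1", l), nnConvBwd(d1, ec$c1, .par(params, sprintf("enc%d_c1", l))))
  }
  g
}

## Soft dice loss over a batch: loss = 1 - (2*sum(p*t)+eps)/(sum(p)+sum(t)+eps).
## Returns loss and d(loss)/d(logit) (gradient through the sigmoid included).
softDiceLoss <- function(prob, target, eps = 1) {
  S <- sum(prob * target); P <- sum(prob); T <- sum(target)
  denom <- P + T + eps
  dicev <- (2 * S + eps) / denom
  dProb <- -(2 * target * denom - (2 * S + eps)) / denom^2
  list(loss = 1 - dicev, dLogit = dProb * prob * (1 - prob))
}
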