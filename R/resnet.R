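## Reduced residual classifier: a 3x3 stem, three residual stages (channels
## doubling, 2x2 max pooling between stages), global average pooling, and a
## 2-neuron softmax head giving the probability of the vacuolated class.
## Each residual block is conv-relu-conv plus a shortcut (1x1 projection when
## the channel count changes), followed by a relu. Internal.

resnetInit <- function(baseFilters, blocksPerStage, cin = 3L) {
  f <- baseFilters * 2L^(0:2)
  p <- list(stem = nnConvInit(cin, f[1]))
  for (s in 1:3) {
    for (b in seq_len(blocksPerStage)) {
      inc <- if (b == 1L && s > 1L) f[s - 1L] else f[s]
      p[[sprintf("s%db%d_c1", s, b)]] <- nnConvInit(inc, f[s])
      ## zero-init the block's second conv: each residual block starts as the
      ## identity, which stabilizes training without normalization layers
      c2 <- nnConvInit(f[s], f[s])
      c2$W[] <- 0
      p[[sprintf("s%db%d_c2", s, b)]] <- c2
      if (inc != f[s]) p[[sprintf("s%db%d_sc", s, b)]] <- nnDenseInit(inc, f[s])
    }
  }
  ## head sees average- and max-pooled global descriptors: average pooling
  ## alone washes out small sparse features like vacuoles
  p[["dense"]] <- nnDenseInit(2L * f[3], 2L)
  flat <- list()
  for (nm in names(p)) {
    flat[[paste0(nm, "_W")]] <- p[[nm]]$W
    flat[[paste0(nm, "_b")]] <- p[[nm]]$b
  }
  flat
}

resnetForward <- function(params, X, blocksPerStage, keepCache = TRUE) {
  cache <- list()
  st <- nnConvFwd(X, .par(params, "stem"))
  sr <- nnReluFwd(st$out)
  if (keepCache) cache$stem <- list(c = st, r = sr)
  A <- sr$out
  for (s in 1:3) {
    if (s > 1L) {
      pl <- nnPoolFwd(A)
      if (keepCache) cache[[sprintf("pool%d", s)]] <- pl
      A <- pl$out
    }
    for (b in seq_len(blocksPerStage)) {
      nm <- sprintf("s%db%d", s, b)
      c1 <- nnConvFwd(A, .par(params, paste0(nm, "_c1")))
      r1 <- nnReluFwd(c1$out)
      c2 <- nnConvFwd(r1$out, .par(params, paste0(nm, "_c2")))
      hasProj <- !is.null(params[[paste0(nm, "_sc_W")]])
      if (hasProj) {
        sc <- nnConv1Fwd(A, .par(params, paste0(nm, "_sc")))
        short <- sc$out
      } else {
        sc <- NULL
        short <- A
      }
      r2 <- nnReluFwd(c2$out + short)
      if (keepCache) cache[[nm]] <- list(c1 = c1, r1 = r1, c2 = c2, sc = sc, r2 = r2)
      A <- r2$out
    }
  }
  ## global average + max pooling over space -> (N, 2C) features
  d <- dim(A)
  Am <- matrix(A, d[1] * d[2], d[3] * d[4])
  gap <- matrix(colMeans(Am), d[3], d[4])
  amax <- max.col(t(Am), ties.method = "first")          # argmax per (n, c)
  gmp <- matrix(Am[cbind(amax, seq_len(d[3] * d[4]))], d[3], d[4])
  G <- cbind(gap, gmp)
  logits <- G %*% params$dense_W + rep(params$dense_b, each = d[3])
  prob <- nnSoftmax(logits)
  list(prob = prob, logits = logits, G = G, stage3 = A, amax = amax,
       cache = cache, dims = d)
}

## Backward from d(loss)/d(logits). When `toStage3Only` is TRUE, stops after
## propagating through the head and returns the gradient at the last
## convolutional stage output (the quantity Grad-CAM pools).
resnetBackward <- function(params, dLogits, fw, blocksPerStage, toStage3Only = FALSE) {
  d <- fw$dims
  g <- list()
  g$dense_W <- crossprod(fw$G, dLogits)
  g$dense_b <- colSums(dLogits)
  dG <- tcrossprod(dLogits, params$dense_W)          # (N, 2C)
  C <- d[4]
  dGap <- dG[, seq_len(C), drop = FALSE]
  dGmp <- dG[, C + seq_len(C), drop = FALSE]
  dA <- array(0, d)
  dA[] <- rep(as.numeric(dGap), each = d[1] * d[2]) / (d[1] * d[2])
  ## route the max-pool part of the gradient to each channel's argmax pixel
  dAm <- matrix(dA, d[1] * d[2], d[3] * C)
  cols <- seq_len(d[3] * C)
  dAm[cbind(fw$amax, cols)] <- dAm[cbind(fw$amax, cols)] + as.numeric(dGmp)
  dA <- array(dAm, d)
  if (toStage3Only) return(dA)
  cache <- fw$cache
  for (s in 3:1) {
    for (b in rev(seq_len(blocksPerStage))) {
      nm <- sprintf("s%db%d", s, b)
      cc <- cache[[nm]]
      dSum <- nnReluBwd(dA, cc$r2)
      d2 <- nnConvBwd(dSum, cc$c2, .par(params, paste0(nm, "_c2")))
      g[[paste0(nm, "_c2_W")]] <- d2$dW; g[[paste0(nm, "_c2_b")]] <- d2$db
      d1pre <- nnReluBwd(d2$dX, cc$r1)
      d1 <- nnConvBwd(d1pre, cc$c1, .par(params, paste0(nm, "_c1")))
      g[[paste0(nm, "_c1_W")]] <- d1$dW; g[[paste0(nm, "_c1_b")]] <- d1$db
      if (!is.null(cc$sc)) {
        dsc <- nnConv1Bwd(dSum, cc$sc, .par(params, paste0(nm, "_sc")))
        g[[paste0(nm, "_sc_W")]] <- dsc$dW; g[[paste0(nm, "_sc_b")]] <- dsc$db
        dA <- d1$dX + dsc$dX
      } else {
        dA <- d1$dX + dSum
      }
    }
    if (s > 1L) dA <- nnPoolBwd(dA, cache[[sprintf("pool%d", s)]])
  }
  dR <- nnReluBwd(dA, cache$stem$r)
  dst <- nnConvBwd(dR, cache$stem$c, .par(params, "stem"))
  g$stem_W <- dst$dW; g$stem_b <- dst$db
  g
}

## Softmax cross-entropy; labels are 1 (vacuolated) / 2 (healthy) column idx
softmaxXent <- function(prob, labels) {
  n <- nrow(prob)
  picked <- prob[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dLogits <- prob
  dLogits[cbind(seq_len(n), labels)] <- dLogits[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dLogits = dLogits / n)
}
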