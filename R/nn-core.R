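## Minimal CPU CNN engine used by the U-Net segmenter and the residual
## classifier. Activations are stored as 4-D arrays with dimensions
## (height, width, batch, channels); convolutions are 3x3 same-padding,
## lowered to matrix multiplication (im2col) so the heavy lifting runs in
## BLAS. Everything here is internal.

nnConvInit <- function(cin, cout, k = 3L) {
  fan <- k * k * cin
  list(W = matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)), fan, cout),
       b = numeric(cout))
}

nnDenseInit <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

.pad1 <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- X
  Xp
}

## (H+2, W+2, N, C) -> (H*W*N) x (9*C) patch matrix, offset-major columns
.im2col <- function(Xp, H, W) {
  N <- dim(Xp)[3]; C <- dim(Xp)[4]
  Z <- matrix(0, H * W * N, 9L * C)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    block <- Xp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE]
    Z[, k * C + seq_len(C)] <- block
    k <- k + 1L
  }
  Z
}

## 3x3 same-padding convolution; returns output and the patch matrix cache
nnConvFwd <- function(X, par) {
  d <- dim(X)
  Z <- .im2col(.pad1(X), d[1], d[2])
  out <- Z %*% par$W
  out <- out + rep(par$b, each = nrow(out))
  list(out = array(out, c(d[1], d[2], d[3], ncol(par$W))), Z = Z, dims = d)
}

nnConvBwd <- function(dOut, cache, par) {
  d <- cache$dims
  dOutM <- matrix(dOut, d[1] * d[2] * d[3], ncol(par$W))
  dW <- crossprod(cache$Z, dOutM)
  db <- colSums(dOutM)
  dZ <- tcrossprod(dOutM, par$W)
  dXp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  C <- d[4]; k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    ri <- dy + seq_len(d[1]); ci <- dx + seq_len(d[2])
    dXp[ri, ci, , ] <- dXp[ri, ci, , , drop = FALSE] +
      array(dZ[, k * C + seq_len(C)], d)
    k <- k + 1L
  }
  list(dX = dXp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE], dW = dW, db = db)
}

## 1x1 convolution (channel mixing), used for decoder up-projections and
## residual shortcuts with channel change
nnConv1Fwd <- function(X, par) {
  d <- dim(X)
  Xm <- matrix(X, prod(d[1:3]), d[4])
  out <- Xm %*% par$W
  out <- out + rep(par$b, each = nrow(out))
  list(out = array(out, c(d[1:3], ncol(par$W))), Xm = Xm, dims = d)
}

nnConv1Bwd <- function(dOut, cache, par) {
  d <- cache$dims
  dOutM <- matrix(dOut, prod(d[1:3]), ncol(par$W))
  list(dX = array(tcrossprod(dOutM, par$W), d),
       dW = crossprod(cache$Xm, dOutM), db = colSums(dOutM))
}

nnReluFwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}
nnReluBwd <- function(dOut, cache) dOut * cache$mask

## 2x2 max pooling (even dimensions assumed, enforced by the architectures)
nnPoolFwd <- function(X) {
  d <- dim(X)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  cand <- list(X[ro, co, , , drop = FALSE], X[ro + 1L, co, , , drop = FALSE],
               X[ro, co + 1L, , , drop = FALSE], X[ro + 1L, co + 1L, , , drop = FALSE])
  out <- cand[[1]]; which <- array(1L, dim(out))
  for (k in 2:4) {
    upd <- cand[[k]] > out
    out[upd] <- cand[[k]][upd]
    which[upd] <- k
  }
  list(out = out, which = which, dims = d)
}

nnPoolBwd <- function(dOut, cache) {
  d <- cache$dims
  dX <- array(0, d)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    sel <- (cache$which == k) * dOut
    dX[ro + offs[[k]][1], co + offs[[k]][2], , ] <-
      dX[ro + offs[[k]][1], co + offs[[k]][2], , , drop = FALSE] + sel
  }
  dX
}

## 2x nearest-neighbor upsampling
nnUpFwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

nnUpBwd <- function(dOut) {
  d <- dim(dOut)
  ro <- seq(1L, d[1], 2L); co <- seq(1L, d[2], 2L)
  dOut[ro, co, , , drop = FALSE] + dOut[ro + 1L, co, , , drop = FALSE] +
    dOut[ro, co + 1L, , , drop = FALSE] + dOut[ro + 1L, co + 1L, , , drop = FALSE]
}

nnConcat <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- A
  out[, , , da[4] + seq_len(db[4])] <- B
  out
}

nnSplit <- function(dOut, c1) {
  d <- dim(dOut)
  list(dA = dOut[, , , seq_len(c1), drop = FALSE],
       dB = dOut[, , , (c1 + 1L):d[4], drop = FALSE])
}

nnSigmoid <- function(x) 1 / (1 + exp(-x))

nnSoftmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Adam optimizer over a flat named list of parameter arrays
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Stack a list of CellImages into the (H, W, N, 3) activation layout
nnStackImages <- function(images) {
  d <- dim(images[[1]]@pixels)
  X <- array(0, c(d[1], d[2], length(images), 3L))
  for (i in seq_along(images)) X[, , i, ] <- images[[i]]@pixels
  X
}

nnStackMasks <- function(masks) {
  d <- dim(masks[[1]]@grid)
  T <- array(0, c(d[1], d[2], length(masks), 1L))
  for (i in seq_along(masks)) T[, , i, 1] <- masks[[i]]@grid
  T
}
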