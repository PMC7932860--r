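# Finite-difference gradient checks for the CNN engine the segmentation and
# classification models run on.

numGrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution backward matches numerical gradients", {
  set.seed(1)
  X <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  par <- withr::with_seed(2, vacuoquant:::nnConvInit(3L, 4L))
  R <- array(rnorm(6 * 6 * 2 * 4), c(6, 6, 2, 4))
  lossOf <- function(Xa, W, b) {
    out <- vacuoquant:::nnConvFwd(Xa, list(W = W, b = b))$out
    sum(out * R)
  }
  fw <- vacuoquant:::nnConvFwd(X, par)
  bw <- vacuoquant:::nnConvBwd(R, fw, par)
  gX <- numGrad(function(v) lossOf(array(v, dim(X)), par$W, par$b), as.numeric(X))
  expect_equal(as.numeric(bw$dX), gX, tolerance = 1e-6)
  gW <- numGrad(function(v) lossOf(X, matrix(v, nrow(par$W)), par$b), as.numeric(par$W))
  expect_equal(as.numeric(bw$dW), gW, tolerance = 1e-6)
  gb <- numGrad(function(v) lossOf(X, par$W, v), par$b)
  expect_equal(as.numeric(bw$db), gb, tolerance = 1e-6)
})

test_that("pooling and upsampling backward are exact adjoint-style routings", {
  set.seed(3)
  X <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  pl <- vacuoquant:::nnPoolFwd(X)
  R <- array(rnorm(length(pl$out)), dim(pl$out))
  bw <- vacuoquant:::nnPoolBwd(R, pl)
  gX <- numGrad(function(v) sum(vacuoquant:::nnPoolFwd(array(v, dim(X)))$out * R),
                as.numeric(X))
  expect_equal(as.numeric(bw), gX, tolerance = 1e-6)
  up <- vacuoquant:::nnUpFwd(X)
  expect_equal(dim(up), c(8, 8, 2, 2))
  R2 <- array(rnorm(length(up)), dim(up))
  gX2 <- numGrad(function(v) sum(vacuoquant:::nnUpFwd(array(v, dim(X))) * R2),
                 as.numeric(X))
  expect_equal(as.numeric(vacuoquant:::nnUpBwd(R2)), gX2, tolerance = 1e-6)
})

test_that("whole-network gradients are correct for a tiny U-Net", {
  set.seed(5)
  depth <- 2L
  params <- withr::with_seed(7, vacuoquant:::unetInit(depth, 2L))
  X <- array(runif(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  Tg <- array(runif(8 * 8) > 0.5, c(8, 8, 1, 1))
  lossOf <- function(p) {
    fw <- vacuoquant:::unetForward(p, X, depth, keepCache = FALSE)
    vacuoquant:::softDiceLoss(fw$prob, Tg)$loss
  }
  fw <- vacuoquant:::unetForward(params, X, depth)
  ls <- vacuoquant:::softDiceLoss(fw$prob, Tg)
  gr <- vacuoquant:::unetBackward(params, ls$dLogit, fw$cache, depth)
  for (nm in c("enc1_c1_W", "dec1_c2_W", "up1_W", "out_W", "enc2_c2_b")) {
    w <- params[[nm]]
    pick <- withr::with_seed(11, sample(length(w), min(5, length(w))))
    for (i in pick) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num <- (lossOf(pp) - lossOf(pm)) / 2e-5
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("whole-network gradients are correct for the residual classifier", {
  set.seed(9)
  params <- withr::with_seed(13, vacuoquant:::resnetInit(2L, 1L))
  # perturb the zero-initialized block convs so their gradients are generic
  for (nm in grep("_c2_W", names(params), value = TRUE))
    params[[nm]] <- matrix(rnorm(length(params[[nm]]), sd = 0.05),
                           nrow(params[[nm]]))
  X <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- c(1L, 2L)
  lossOf <- function(p) {
    fw <- vacuoquant:::resnetForward(p, X, 1L, keepCache = FALSE)
    vacuoquant:::softmaxXent(fw$prob, y)$loss
  }
  fw <- vacuoquant:::resnetForward(params, X, 1L)
  ls <- vacuoquant:::softmaxXent(fw$prob, y)
  gr <- vacuoquant:::resnetBackward(params, ls$dLogits, fw, 1L)
  for (nm in c("stem_W", "s1b1_c1_W", "s2b1_sc_W", "s3b1_c2_W", "dense_W", "dense_b")) {
    w <- params[[nm]]
    pick <- withr::with_seed(17, sample(length(w), min(4, length(w))))
    for (i in pick) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num <- (lossOf(pp) - lossOf(pm)) / 2e-5
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})
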