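test_that("Passing-Bablok recovers exact fits and the hand-computed case", {
  fit <- passingBablok(pairedMeasurements(1:10, 1:10), 199, seed = 1)
  expect_equal(fit@slope, 1)
  expect_equal(fit@intercept, 0)
  fit2 <- passingBablok(pairedMeasurements(1:10, 2 * (1:10) + 1), 199, seed = 1)
  expect_equal(fit2@slope, 2)
  expect_equal(fit2@intercept, 1)
  # six pairwise slopes {0.8, 1.05, 0.9333, 1.3, 1.0, 0.7}; even-count
  # shifted median = (0.93333 + 1)/2; intercept = median of residuals
  fit3 <- passingBablok(pairedMeasurements(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9)),
                        199, seed = 1)
  expect_equal(fit3@slope, 29 / 30, tolerance = 1e-12)
  expect_equal(fit3@intercept, 1 / 12, tolerance = 1e-12)
  expect_equal(fit3@nPairwiseSlopes, 6L)
})

test_that("Passing-Bablok matches the brute-force all-pairs oracle", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    x <- round(runif(n, 0, 50), 1)
    y <- 0.8 * x + rnorm(n, sd = 3)
    fit <- passingBablok(pairedMeasurements(x, y), 49, seed = rep)
    oracle <- bruteForcePB(x, y)
    expect_equal(fit@slope, oracle$slope)
    expect_equal(fit@intercept, oracle$intercept)
  }
})

test_that("Passing-Bablok is scale-equivariant and recovers simulated slopes", {
  set.seed(5)
  x <- runif(40, 5, 60)
  y <- 1.7 * x + rnorm(40, sd = 2)
  f1 <- passingBablok(pairedMeasurements(x, y), 99, seed = 3)
  f2 <- passingBablok(pairedMeasurements(3 * x, 3 * y), 99, seed = 3)
  expect_equal(f2@slope, f1@slope)
  expect_equal(f2@intercept, 3 * f1@intercept, tolerance = 1e-10)
  # parameter recovery with noise on both axes at n = 200
  set.seed(11)
  t <- runif(200, 0, 100)
  xs <- t + rnorm(200, sd = 2)
  ys <- 5 + 0.9 * t + rnorm(200, sd = 2)
  fr <- passingBablok(pairedMeasurements(xs, ys), 49, seed = 1)
  expect_equal(fr@slope, 0.9, tolerance = 0.05)
  # degenerate and undersized inputs
  expect_error(passingBablok(pairedMeasurements(1:2, 1:2)), class = "vq_parameter_error")
  expect_error(passingBablok(pairedMeasurements(c(2, 2, 2), c(1, 2, 3))),
               class = "vq_degenerate_error")
})

test_that("bootstrap CIs are seeded, contain the estimate, and use 999 draws by default", {
  set.seed(21)
  x <- runif(20, 0, 40); y <- x + rnorm(20)
  f1 <- passingBablok(pairedMeasurements(x, y), seed = 7)
  f2 <- passingBablok(pairedMeasurements(x, y), seed = 7)
  expect_identical(f1@slopeCI, f2@slopeCI)
  expect_equal(f1@bootstrapSamples, 999L)
  expect_true(f1@slopeCI[1] <= f1@slope && f1@slope <= f1@slopeCI[2])
  expect_true(f1@interceptCI[1] <= f1@intercept && f1@intercept <= f1@interceptCI[2])
})

test_that("Bland-Altman statistics follow the n-1 formula and antisymmetry", {
  ba <- blandAltman(pairedMeasurements(c(3, 5), c(3, 3)))  # differences 0, 2
  expect_equal(ba@meanDifference, 1)
  expect_equal(ba@sdDifference, sqrt(2))
  expect_equal(ba@loa, c(1 - 1.96 * sqrt(2), 1 + 1.96 * sqrt(2)))
  same <- blandAltman(pairedMeasurements(1:5, 1:5))
  expect_equal(same@meanDifference, 0)
  expect_equal(same@loa, c(0, 0))
  const <- blandAltman(pairedMeasurements(2:6, 1:5))       # all differences 1
  expect_equal(const@loa, c(1, 1))
  set.seed(8)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(blandAltman(pairedMeasurements(x, y))@meanDifference,
               -blandAltman(pairedMeasurements(y, x))@meanDifference)
  expect_error(blandAltman(pairedMeasurements(1, 1)), class = "vq_parameter_error")
})

test_that("Pearson correlation matches hand computation and flags degeneracy", {
  expect_equal(pearsonR(pairedMeasurements(1:5, 1:5)), 1)
  expect_equal(pearsonR(pairedMeasurements(1:5, 5:1)), -1)
  # hand computation: r = 3 / sqrt(2 * 42/9)
  expect_equal(pearsonR(pairedMeasurements(c(1, 2, 3), c(1, 2, 4))),
               3 / sqrt(2 * 42 / 9))
  expect_error(pearsonR(pairedMeasurements(c(1, 1, 1), 1:3)),
               class = "vq_degenerate_error")
})

test_that("Levene W matches the hand-computed case and the reference implementation", {
  lv <- leveneTest(list(a = c(1, 2, 4), b = c(2, 3, 9)))
  expect_equal(lv@W, 128 / 31, tolerance = 1e-10)
  expect_equal(lv@dfBetween, 1L)
  expect_equal(lv@dfWithin, 4L)
  # cross-check against car's mean-centered Levene test
  set.seed(31)
  vals <- list(rnorm(10), rnorm(12, sd = 2), rnorm(9, sd = 0.5))
  lv2 <- leveneTest(vals)
  ref <- car::leveneTest(unlist(vals),
                         factor(rep(seq_along(vals), lengths(vals))), center = mean)
  expect_equal(lv2@W, ref$`F value`[1])
  expect_equal(lv2@pValue, ref$`Pr(>F)`[1])
  # identical groups -> W = 0, p = 1
  z <- leveneTest(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(z@W, 0)
  expect_equal(z@pValue, 1)
  # invariant under a constant shift of one group
  lv3 <- leveneTest(lapply(seq_along(vals), function(i) vals[[i]] + (i == 2) * 100))
  expect_equal(lv3@W, lv2@W)
  expect_error(leveneTest(list(c(1, 2), c(3))), class = "vq_parameter_error")
  expect_error(leveneTest(list(c(1, 1, 1), c(2, 2))), class = "vq_degenerate_error")
})

test_that("the full method comparison handles agreement, noise, and JSON round-trips", {
  # full agreement surfaces degeneracies as flags, not errors
  v <- c(10, 20, 30, 40)
  cmp <- compareMethods(v, v, v, bootstrapSamples = 49, seed = 1)
  expect_true("levene" %in% cmp@flags)
  expect_equal(cmp@passingBablok@slope, 1)
  expect_equal(cmp@blandAltmanAuto@meanDifference, 0)
  # simulated raters with SD 2 percentage points around a shared truth:
  # differences have comparable variance, so Levene should not reject
  set.seed(77)
  truth <- runif(40, 0, 60)
  auto <- truth + rnorm(40, sd = 2)
  m1 <- truth + rnorm(40, sd = 2)
  m2 <- truth + rnorm(40, sd = 2)
  cmp2 <- compareMethods(auto, m1, m2, bootstrapSamples = 199, seed = 5)
  expect_gt(cmp2@levene@pValue, 0.05)
  expect_gt(cmp2@pearson, 0.97)
  expect_true(cmp2@passingBablok@slope > 0.9 && cmp2@passingBablok@slope < 1.1)
  # lossless JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(cmp2, path)
  back <- readReport(path)
  expect_equal(back@passingBablok@slope, cmp2@passingBablok@slope)
  expect_equal(back@passingBablok@slopeCI, cmp2@passingBablok@slopeCI)
  expect_equal(back@levene@pValue, cmp2@levene@pValue)
  expect_equal(back@blandAltmanAuto@loa, cmp2@blandAltmanAuto@loa)
  expect_equal(back@pearson, cmp2@pearson)
})
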