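test_that("softmax probabilities always normalize, even on degenerate input", {
  params <- withr::with_seed(1, vacuoquant:::resnetInit(4L, 1L))
  bundle <- new("ClsModelBundle", weights = params, config = tinyClsConfig(),
                validationAccuracy = 0, history = data.frame())
  cell <- generateCell(tinyParams(), TRUE, seed = 2)
  p <- classify(bundle, maskWithTruth(cell))
  expect_s4_class(p, "ProbabilityVector")
  expect_equal(p@pVacuolated + p@pHealthy, 1, tolerance = 1e-9)
  # an all-zero image still yields a valid probability vector
  zero <- cellImage(array(0, c(32, 32, 3)))
  pz <- classify(bundle, zero)
  expect_equal(pz@pVacuolated + pz@pHealthy, 1, tolerance = 1e-9)
  expect_error(classify(bundle, cellImage(array(0.5, c(30, 30, 3)))),
               class = "vq_shape_error")
})

test_that("the decision rule is inclusive at tau and monotone", {
  tau <- decisionThreshold(0.65)
  expect_true(isVacuolated(probabilityVector(0.65), tau))   # >= is inclusive
  expect_false(isVacuolated(probabilityVector(0.649), tau))
  expect_true(isVacuolated(probabilityVector(1.0), tau))
  expect_true(isVacuolated(probabilityVector(1.0), decisionThreshold(0.99)))
  # monotone: raising p never flips a positive call to negative
  ps <- seq(0, 1, by = 0.05)
  calls <- vapply(ps, function(p) isVacuolated(probabilityVector(p), tau), logical(1))
  expect_true(all(diff(calls) >= 0))
  expect_error(decisionThreshold(1.5), "tau")
})

test_that("classifier training demands two classes and a positive epoch count", {
  expect_error(clsTrainConfig(epochs = 0), class = "vq_parameter_error")
  onlyVac <- lapply(1:10, function(i) generateCell(tinyParams(), TRUE, seed = i))
  expect_error(trainClassifier(lapply(onlyVac, maskWithTruth), tinyClsConfig()),
               class = "vq_data_error")
  unlabeled <- lapply(onlyVac, function(x) cellImage(x@pixels))
  expect_error(trainClassifier(unlabeled, tinyClsConfig()), class = "vq_data_error")
})

test_that("shuffled labels leave validation accuracy at chance level", {
  pool <- generateCellPool(60L, tinyParams(), seed = 5)
  masked <- lapply(pool, maskWithTruth)
  shuffled <- withr::with_seed(99, {
    labs <- sample(vapply(masked, cellLabel, character(1)))
    lapply(seq_along(masked), function(i) {
      x <- masked[[i]]
      initialize(x, label = labs[i])
    })
  })
  b <- trainClassifier(shuffled, tinyClsConfig(seed = 6, epochs = 3L),
                       maxRestarts = 1L)
  expect_gte(b@validationAccuracy, 0.2)
  expect_lte(b@validationAccuracy, 0.8)
})

test_that("Grad-CAM maps are normalized, input-sized, and degenerate-safe", {
  params <- withr::with_seed(3, vacuoquant:::resnetInit(4L, 1L))
  bundle <- new("ClsModelBundle", weights = params, config = tinyClsConfig(),
                validationAccuracy = 0, history = data.frame())
  cell <- maskWithTruth(generateCell(tinyParams(), TRUE, seed = 8))
  m <- gradCam(bundle, cell, "vacuolated")
  expect_identical(dim(m@heatmap), dim(cell@pixels)[1:2])
  expect_gte(min(m@heatmap), 0)
  expect_lte(max(m@heatmap), 1)
  if (max(m@heatmap) > 0) expect_equal(max(m@heatmap), 1)
  # zero dense weights for the target class kill every channel weight: the
  # raw map is identically zero and must come back all zero, not NaN
  dead <- params
  dead$dense_W[, 1] <- 0
  bz <- new("ClsModelBundle", weights = dead, config = tinyClsConfig(),
            validationAccuracy = 0, history = data.frame())
  mz <- gradCam(bz, cell, "vacuolated")
  expect_true(all(mz@heatmap == 0))
  expect_error(gradCam(new("ClsModelBundle", weights = list(),
                           config = tinyClsConfig(), validationAccuracy = 0,
                           history = data.frame()), cell),
               class = "vq_model_error")
})

test_that("Grad-CAM overlays write a PNG and a raw CSV map", {
  params <- withr::with_seed(4, vacuoquant:::resnetInit(4L, 1L))
  bundle <- new("ClsModelBundle", weights = params, config = tinyClsConfig(),
                validationAccuracy = 0, history = data.frame())
  cell <- maskWithTruth(generateCell(tinyParams(), TRUE, seed = 9))
  m <- gradCam(bundle, cell)
  png <- withr::local_tempfile(fileext = ".png")
  writeGradCamOverlay(m, cell, png)
  expect_true(file.exists(png))
  csv <- sub("\\.png$", ".csv", png)
  raw <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(dim(raw), dim(m@heatmap))
  expect_equal(unname(raw[1, 1]), m@heatmap[1, 1], tolerance = 1e-12)
})

test_that("cytoplasm masking helps when the background carries clutter", {
  # distractor discs in the background mimic vacuole-like structures outside
  # the cell; the masked-input classifier should beat the unmasked one under
  # an identical architecture, seed and budget
  p <- syntheticParams(imageSize = 64L, clutterCount = 8L)
  pool <- generateCellPool(160L, p, seed = 21)
  cfg <- clsTrainConfig(epochs = 6L, baseFilters = 8L, blocksPerStage = 1L,
                        batchSize = 16L, seed = 22L)
  accMasked <- trainClassifier(lapply(pool, maskWithTruth), cfg,
                               maxRestarts = 1L)@validationAccuracy
  accRaw <- trainClassifier(pool, cfg, maxRestarts = 1L)@validationAccuracy
  expect_gt(accMasked, accRaw)
})
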