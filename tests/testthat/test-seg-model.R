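test_that("the train/validation split follows the floor rule and is reproducible", {
  sp <- splitDataset(as.list(1:100), 0.8, seed = 1)
  expect_length(sp$train, 80L)
  expect_length(sp$validation, 20L)
  sp5 <- splitDataset(as.list(1:5), 0.8, seed = 2)
  expect_length(sp5$train, 4L)
  expect_length(sp5$validation, 1L)
  expect_length(intersect(unlist(sp$train), unlist(sp$validation)), 0L)
  expect_identical(splitDataset(as.list(1:100), 0.8, seed = 9),
                   splitDataset(as.list(1:100), 0.8, seed = 9))
  expect_error(splitDataset(list(1), 0.8), class = "vq_parameter_error")
})

test_that("segmenter training rejects degenerate configs and missing masks", {
  expect_error(segTrainConfig("cell", epochs = 0), class = "vq_parameter_error")
  expect_error(segTrainConfig("cell", splitFraction = 1.2), class = "vq_parameter_error")
  cells <- generateCellPool(4L, tinyParams(), seed = 1)
  stripped <- lapply(cells, function(x) cellImage(x@pixels, label = x@label))
  expect_error(trainSegmenter(stripped, tinySegConfig("cell")), class = "vq_data_error")
})

test_that("a briefly trained segmenter outperforms an untrained one and predicts binary masks", {
  cells <- generateCellPool(40L, tinyParams(), seed = 2)
  cfg <- tinySegConfig("cell", seed = 3, epochs = 3L)
  bundle <- trainSegmenter(cells, cfg)
  expect_true(all(is.finite(bundle@history$loss)))
  expect_equal(nrow(bundle@history), 3L)
  untrained <- new("SegModelBundle",
                   weights = withr::with_seed(3, vacuoquant:::unetInit(2L, 4L)),
                   config = cfg, validationDice = 0,
                   history = data.frame())
  held <- generateCell(tinyParams(), TRUE, seed = 999)
  predTrained <- predictMask(bundle, held)
  expect_type(maskGrid(predTrained), "logical")
  expect_identical(dim(maskGrid(predTrained)), dim(held@pixels)[1:2])
  diceOf <- function(b) {
    pred <- predictMask(b, held)
    if (nForeground(pred) == 0) 0 else diceValue(dice(pred, cellMask(held)))
  }
  expect_gt(diceOf(bundle), diceOf(untrained))
  # a uniform background image still yields a defined binary output
  flat <- cellImage(array(0.93, c(32, 32, 3)))
  expect_s4_class(predictMask(bundle, flat), "BinaryMask")
  # dimensions incompatible with the pooling depth are refused
  odd <- cellImage(array(0.5, c(31, 31, 3)))
  expect_error(predictMask(bundle, odd), class = "vq_shape_error")
})

test_that("cytoplasm segmentation composes the two models and surfaces failures", {
  cells <- generateCellPool(40L, tinyParams(), seed = 4)
  cellB <- trainSegmenter(cells, tinySegConfig("cell", seed = 5, epochs = 3L))
  nucB <- trainSegmenter(cells, tinySegConfig("nucleus", seed = 6, epochs = 3L))
  held <- generateCell(tinyParams(), FALSE, seed = 1234)
  seg <- segmentCytoplasm(cellB, nucB, held)
  # reduces to the mask-ops contracts: masked image retains only cytoplasm pixels
  keep <- array(maskGrid(seg$mask), dim(held@pixels))
  expect_identical(seg$masked@pixels[keep], held@pixels[keep])
  expect_true(all(seg$masked@pixels[!keep] == 0))
  # a nucleus model that covers the whole cell leaves no cytoplasm
  allOn <- new("SegModelBundle", weights = cellB@weights,
               config = cellB@config, validationDice = 1, history = data.frame())
  expect_error(segmentCytoplasm(cellB, allOn, held), class = "vq_segfail_error")
  # an empty cell prediction is a segmentation failure too
  neverCell <- new("SegModelBundle",
                   weights = lapply(cellB@weights, function(w) w * 0 - 1e3 * (length(dim(w)) == 0)),
                   config = cellB@config, validationDice = 0, history = data.frame())
  expect_error(segmentCytoplasm(neverCell, nucB, held), class = "vq_segfail_error")
})

test_that("model bundles survive the save/load round trip", {
  cells <- generateCellPool(30L, tinyParams(), seed = 7)
  bundle <- trainSegmenter(cells, tinySegConfig("nucleus", seed = 8, epochs = 2L))
  dir <- withr::local_tempdir()
  saveModelBundle(bundle, dir)
  back <- loadModelBundle(dir)
  expect_equal(back@validationDice, bundle@validationDice)
  expect_equal(back@config@target, "nucleus")
  held <- generateCell(tinyParams(), TRUE, seed = 55)
  expect_identical(maskGrid(predictMask(back, held)),
                   maskGrid(predictMask(bundle, held)))
})
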