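test_that("dice follows the overlap formula and its edge anchors", {
  mk <- function(v) binaryMask(matrix(v, 4, 4))
  a <- mk(c(rep(TRUE, 4), rep(FALSE, 12)))
  b <- mk(c(rep(FALSE, 12), rep(TRUE, 4)))
  # identical nonempty masks -> complete overlap
  expect_equal(diceValue(dice(a, a)), 1)
  # disjoint nonempty masks -> no overlap
  expect_equal(diceValue(dice(a, b)), 0)
  # 4 + 4 foreground with overlap 2 -> 2*2/(4+4) = 0.5, counted by hand
  c2 <- mk(c(rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 10)))
  d <- dice(a, c2)
  expect_equal(diceValue(d), 0.5)
  expect_equal(d@overlapPixels, 2L)
  expect_equal(d@totalPixels, 8L)
})

test_that("dice is symmetric and rejects degenerate or mismatched input", {
  set.seed(41)
  for (i in 1:10) {
    a <- binaryMask(matrix(runif(64) > 0.6, 8, 8))
    b <- binaryMask(matrix(runif(64) > 0.6, 8, 8))
    if (nForeground(a) + nForeground(b) == 0) next
    expect_equal(diceValue(dice(a, b)), diceValue(dice(b, a)))
  }
  empty <- binaryMask(matrix(FALSE, 8, 8))
  expect_error(dice(empty, empty), class = "vq_degenerate_error")
  expect_error(dice(binaryMask(matrix(TRUE, 8, 8)), binaryMask(matrix(TRUE, 4, 4))),
               class = "vq_shape_error")
})

test_that("cytoplasm mask is cell minus nucleus", {
  cell <- binaryMask(matrix(TRUE, 3, 3))
  nucleus <- binaryMask(matrix(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                 FALSE, FALSE, FALSE), 3, 3))
  ring <- cytoplasmMask(cell, nucleus)
  expect_equal(nForeground(ring), 8L)          # the 8-pixel ring
  expect_false(maskGrid(ring)[2, 2])
  # nucleus identical to cell -> empty; nucleus empty -> cell unchanged
  expect_equal(nForeground(cytoplasmMask(cell, cell)), 0L)
  expect_identical(maskGrid(cytoplasmMask(cell, binaryMask(matrix(FALSE, 3, 3)))),
                   maskGrid(cell))
  # result never contains a nucleus pixel; cytoplasm + nucleus restricted to
  # the cell recovers the cell
  set.seed(7)
  for (i in 1:10) {
    cg <- matrix(runif(100) > 0.4, 10, 10)
    ng <- cg & matrix(runif(100) > 0.5, 10, 10)
    cy <- maskGrid(cytoplasmMask(binaryMask(cg), binaryMask(ng)))
    expect_false(any(cy & ng))
    expect_identical(cy | (ng & cg), cg)
  }
})

test_that("applyMask blacks out exactly the background and is idempotent", {
  set.seed(3)
  px <- array(runif(3 * 3 * 3, min = 0.2, max = 0.9), c(3, 3, 3))
  img <- cellImage(px)
  ring <- cytoplasmMask(binaryMask(matrix(TRUE, 3, 3)),
                        binaryMask(matrix(c(rep(FALSE, 4), TRUE, rep(FALSE, 4)), 3, 3)))
  out <- applyMask(img, ring)
  expect_equal(out@pixels[2, 2, ], c(0, 0, 0))
  keep <- which(array(maskGrid(ring), dim(px)))
  expect_identical(out@pixels[keep], px[keep])
  # all-foreground leaves the image unchanged; all-background zeroes it
  expect_identical(applyMask(img, binaryMask(matrix(TRUE, 3, 3)))@pixels, px)
  expect_true(all(applyMask(img, binaryMask(matrix(FALSE, 3, 3)))@pixels == 0))
  # idempotent
  expect_identical(applyMask(out, ring)@pixels, out@pixels)
})

test_that("masks and images survive the PNG round trip", {
  g <- matrix(runif(32 * 32) > 0.5, 32, 32)
  p1 <- withr::local_tempfile(fileext = ".png")
  writeMaskPNG(binaryMask(g), p1)
  expect_identical(maskGrid(readMaskPNG(p1)), g)
  cell <- generateCell(tinyParams(), vacuolated = TRUE, seed = 5)
  p2 <- withr::local_tempfile(fileext = ".png")
  writeImagePNG(cell, p2)
  back <- readImagePNG(p2)
  # 8-bit quantization: within half a gray level
  expect_lt(max(abs(back@pixels - cell@pixels)), 1 / 255)
  expect_error(readMaskPNG("no/such/file.png"), class = "vq_io_error")
})
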