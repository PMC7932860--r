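test_that("generated cells honor the mask nesting and label invariants", {
  p <- tinyParams()
  for (seed in c(3, 11, 27, 55)) {
    for (vac in c(TRUE, FALSE)) {
      cell <- generateCell(p, vacuolated = vac, seed = seed)
      cg <- maskGrid(cellMask(cell)); ng <- maskGrid(nucleusMask(cell))
      vg <- maskGrid(vacuoleMask(cell))
      expect_false(any(ng & !cg))             # nucleus inside cell
      expect_false(any(vg & !(cg & !ng)))     # vacuoles inside cytoplasm
      expect_identical(cellLabel(cell) == "vacuolated", vac)
      expect_identical(any(vg), vac)          # label <-> nonempty vacuole mask
      expect_true(any(cg & !ng))              # a cytoplasm rim always exists
    }
  }
})

test_that("healthy cells have no vacuoles and generation is bit-reproducible", {
  p <- tinyParams()
  expect_equal(nForeground(vacuoleMask(generateCell(p, FALSE, seed = 7))), 0L)
  a <- generateCell(p, TRUE, seed = 7)
  b <- generateCell(p, TRUE, seed = 7)
  expect_identical(a@pixels, b@pixels)
  expect_identical(maskGrid(vacuoleMask(a)), maskGrid(vacuoleMask(b)))
  expect_false(identical(a@pixels, generateCell(p, TRUE, seed = 8)@pixels))
})

test_that("vacuoles are pale clearings against the surrounding cytoplasm", {
  p <- studyParams()
  for (seed in c(2, 9, 31)) {
    cell <- generateCell(p, TRUE, seed = seed)
    vg <- maskGrid(vacuoleMask(cell))
    cyto <- maskGrid(cellMask(cell)) & !maskGrid(nucleusMask(cell)) & !vg
    d <- dim(cell@pixels)
    inVac <- mean(cell@pixels[array(vg, d)])
    inCyto <- mean(cell@pixels[array(cyto, d)])
    expect_gt(inVac, inCyto)
  }
})

test_that("smears carry exactly the requested number of vacuolated cells", {
  p <- tinyParams()
  sm <- generateSmear(10, 0.2, p, seed = 1)
  expect_equal(sum(sm$manifest$label == "vacuolated"), 2L)
  expect_equal(sum(generateSmear(5, 0, p, seed = 1)$manifest$label == "vacuolated"), 0L)
  # round(40 x 0.33) = 13
  expect_equal(sum(generateSmear(40, 0.33, p, seed = 9)$manifest$label == "vacuolated"), 13L)
  # manifest rows align with cell labels after the deterministic shuffle
  labs <- vapply(sm$cells, cellLabel, character(1))
  expect_identical(labs, sm$manifest$label)
  expect_error(generateSmear(0, 0.5, p), class = "vq_parameter_error")
})

test_that("dataset generation writes reproducible files and faithful manifests", {
  p <- tinyParams()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateDataset(2, c(0, 0.5), p, d1, cellsPerSmear = 6L, seed = 4)
  m2 <- generateDataset(2, c(0, 0.5), p, d2, cellsPerSmear = 6L, seed = 4)
  expect_equal(nrow(m1), 12L)
  expect_identical(m1$label, m2$label)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  sums1 <- unname(tools::md5sum(file.path(d1, f1)))
  sums2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(sums1, sums2)
  # all-vacuolated smear
  m3 <- generateDataset(1, 1.0, p, withr::local_tempdir(), cellsPerSmear = 6L, seed = 4)
  expect_true(all(m3$label == "vacuolated"))
  # masks on disk agree with freshly generated ground truth
  cellPng <- readMaskPNG(file.path(d1, m1$cell_mask[1]))
  expect_gt(nForeground(cellPng), 0)
})

test_that("impossible geometry is rejected as a parameter error", {
  expect_error(syntheticParams(imageSize = 32, cellRadiusRange = c(10, 20)),
               class = "vq_parameter_error")
  expect_error(syntheticParams(vacuoleCountRange = c(0L, 2L)),
               class = "vq_parameter_error")
  expect_error(syntheticParams(nucleusAreaFractionRange = c(0.5, 1.2)),
               class = "vq_parameter_error")
})
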