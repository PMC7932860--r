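test_that("identity config returns the input unchanged and seeds reproduce", {
  cell <- generateCell(tinyParams(), TRUE, seed = 3)
  idcfg <- augmentationConfig(factor = 1, rotationMaxDeg = 0, shiftMaxFraction = 0,
                              shearMaxDeg = 0, zoomRange = c(1, 1),
                              allowFlips = c(FALSE, FALSE))
  expect_identical(augmentExample(cell, idcfg, seed = 5)@pixels, cell@pixels)
  cfg <- augmentationConfig(seed = 2)
  a1 <- augmentExample(cell, cfg, seed = 9)
  a2 <- augmentExample(cell, cfg, seed = 9)
  expect_identical(a1@pixels, a2@pixels)
  expect_identical(maskGrid(cellMask(a1)), maskGrid(cellMask(a2)))
})

test_that("masks co-transform with the image and keep their nesting", {
  cfg <- augmentationConfig(seed = 4)
  for (seed in c(1, 8, 21, 33, 47)) {
    cell <- generateCell(tinyParams(), TRUE, seed = seed)
    a <- augmentExample(cell, cfg, seed = seed * 13)
    cg <- maskGrid(cellMask(a)); ng <- maskGrid(nucleusMask(a))
    vg <- maskGrid(vacuoleMask(a))
    expect_false(any(ng & !cg))
    expect_false(any(vg & !(cg & !ng)))
    expect_true(all(dim(a@pixels) == dim(cell@pixels)))
    # masks stay strictly binary after warping
    expect_type(cg, "logical")
    # labels are invariant under augmentation
    expect_identical(cellLabel(a), cellLabel(cell))
    # the same transform applied twice to the same mask agrees perfectly
    b <- augmentExample(cell, cfg, seed = seed * 13)
    expect_equal(diceValue(dice(cellMask(a), cellMask(b))), 1)
  }
})

test_that("augmentation expands a dataset by exactly the configured factor", {
  cells <- lapply(1:10, function(i) generateCell(tinyParams(), i %% 2 == 0, seed = i))
  out <- augmentDataset(cells, augmentationConfig(factor = 3, seed = 1))
  expect_length(out, 30L)
  # every output traceable to its source
  expect_identical(names(out)[1:4], c("1_aug1", "1_aug2", "1_aug3", "2_aug1"))
  expect_length(augmentDataset(cells[1], augmentationConfig(factor = 1)), 1L)
  expect_error(augmentDataset(list(), augmentationConfig()), class = "vq_parameter_error")
})

test_that("augmented copies differ from each other but preserve gross structure", {
  cell <- generateCell(tinyParams(), TRUE, seed = 6)
  out <- augmentDataset(list(cell), augmentationConfig(factor = 5, seed = 3))
  pix <- vapply(out, function(x) mean(x@pixels), numeric(1))
  expect_gt(length(unique(pix)), 1L)
  # cell area is roughly preserved under mild zoom (0.9-1.1 scale)
  areas <- vapply(out, function(x) nForeground(cellMask(x)), numeric(1))
  base <- nForeground(cellMask(cell))
  expect_true(all(areas > 0.6 * base & areas < 1.5 * base))
})
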