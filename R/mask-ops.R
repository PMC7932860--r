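#' @include AllClasses.R AllGenerics.R
NULL

.checkSameDim <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b)))
    vqError(sprintf("%s have mismatched dimensions (%s vs %s)", what,
                    paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
            "vq_shape_error")
}

#' Dice similarity coefficient between two binary masks
#'
#' dice = 2 * |A intersect B| / (|A| + |B|), where |.| counts foreground
#' pixels: 0 indicates no spatial overlap between the two masks and 1
#' complete overlap. Used to score predicted segmentation masks against
#' manually drawn (or ground-truth) masks.
#'
#' Two empty masks leave the score undefined (0/0); this is raised as a
#' degenerate-score error rather than silently defined, because an empty
#' predicted cell mask signals segmentation failure and must surface.
#'
#' @param a,b \linkS4class{BinaryMask} objects of identical dimensions.
#' @return a \linkS4class{DiceScore}.
#' @examples
#' a <- binaryMask(matrix(c(rep(TRUE, 4), rep(FALSE, 12)), 4, 4))
#' diceValue(dice(a, a))  # 1
#' @export
setMethod("dice", signature("BinaryMask", "BinaryMask"), function(a, b) {
  ga <- a@grid; gb <- b@grid
  .checkSameDim(ga, gb)
  overlap <- sum(ga & gb)
  total <- sum(ga) + sum(gb)
  if (total == 0L)
    vqError("dice undefined: both masks are empty", "vq_degenerate_error")
  new("DiceScore", value = 2 * overlap / total,
      overlapPixels = as.integer(overlap), totalPixels = as.integer(total))
})

#' Cytoplasm mask by subtraction
#'
#' The cytoplasm segmentation mask is constructed by subtracting the nucleus
#' mask from the cell mask: foreground where the cell mask is foreground and
#' the nucleus mask is not.
#'
#' @param cell,nucleus \linkS4class{BinaryMask} objects of identical dimensions.
#' @return a \linkS4class{BinaryMask}.
#' @export
setMethod("cytoplasmMask", signature("BinaryMask", "BinaryMask"), function(cell, nucleus) {
  .checkSameDim(cell@grid, nucleus@grid)
  binaryMask(cell@grid & !nucleus@grid)
})

#' Black out an image outside a mask
#'
#' Sets every pixel outside the mask foreground to 0 in all channels and
#' leaves pixels inside untouched — e.g. blacking out all of the image except
#' the cytoplasm before classification.
#'
#' @param image a \linkS4class{CellImage}.
#' @param mask a \linkS4class{BinaryMask} matching the image dimensions.
#' @return a \linkS4class{CellImage} with the same masks/label attached.
#' @export
setMethod("applyMask", signature("CellImage", "BinaryMask"), function(image, mask) {
  px <- image@pixels
  .checkSameDim(px[, , 1], mask@grid, "image and mask")
  keep <- array(mask@grid, dim = dim(px))  # recycled across channels
  px[!keep] <- 0
  initialize(image, pixels = px)
})

## ---- mask / image PNG round-trip ----
## Masks are stored as 8-bit grayscale PNG (0 = background, 255 = foreground)
## and thresholded at 128 on read for round-trip safety across image
## libraries. Images are 8-bit RGB PNG.

#' Read and write binary masks and cell images as PNG
#'
#' @param path file path.
#' @param mask a \linkS4class{BinaryMask}.
#' @param image a \linkS4class{CellImage} (masks/labels are not stored in the
#'   PNG; use the dataset manifest for those).
#' @return readers return the parsed object; writers return the path invisibly.
#' @name maskPNG
NULL

#' @rdname maskPNG
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(ifelse(mask@grid, 1, 0), path)
  invisible(path)
}

#' @rdname maskPNG
#' @export
readMaskPNG <- function(path) {
  if (!file.exists(path)) vqError(sprintf("mask file not found: %s", path), "vq_io_error")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  binaryMask(x >= 128 / 255)
}

#' @rdname maskPNG
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(image@pixels, path)
  invisible(path)
}

#' @rdname maskPNG
#' @export
readImagePNG <- function(path) {
  if (!file.exists(path)) vqError(sprintf("image file not found: %s", path), "vq_io_error")
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  cellImage(x)
}
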