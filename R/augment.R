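#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct an augmentation configuration
#'
#' The five geometric transform families — rotation, shifting, shearing,
#' zooming and flipping — with mild default magnitudes chosen to keep the
#' whole cell inside the frame.
#'
#' @param factor copies per original; default 20.
#' @param rotationMaxDeg default 30 (rotation drawn in +/- this range).
#' @param shiftMaxFraction default 0.1 of the image side per axis.
#' @param shearMaxDeg default 10.
#' @param zoomRange default c(0.9, 1.1).
#' @param allowFlips horizontal/vertical flip flags; default both TRUE.
#' @param seed integer.
#' @return an \linkS4class{AugmentationConfig}.
#' @export
augmentationConfig <- function(factor = 20L, rotationMaxDeg = 30, shiftMaxFraction = 0.1,
                               shearMaxDeg = 10, zoomRange = c(0.9, 1.1),
                               allowFlips = c(TRUE, TRUE), seed = 1L) {
  tryCatch(
    new("AugmentationConfig", factor = as.integer(factor),
        rotationMaxDeg = rotationMaxDeg, shiftMaxFraction = shiftMaxFraction,
        shearMaxDeg = shearMaxDeg, zoomRange = zoomRange,
        allowFlips = allowFlips, seed = as.integer(seed)),
    error = function(e) vqError(conditionMessage(e), "vq_parameter_error"))
}

## Sample one transform from the config; returns the 2x2 linear part (about
## the image center) and the translation, plus whether it is the identity.
.sampleTransform <- function(config, side) {
  theta <- if (config@rotationMaxDeg > 0)
    runif(1, -config@rotationMaxDeg, config@rotationMaxDeg) * pi / 180 else 0
  shift <- if (config@shiftMaxFraction > 0)
    runif(2, -config@shiftMaxFraction, config@shiftMaxFraction) * side else c(0, 0)
  shear <- if (config@shearMaxDeg > 0)
    tan(runif(1, -config@shearMaxDeg, config@shearMaxDeg) * pi / 180) else 0
  zoom <- runif(1, config@zoomRange[1], config@zoomRange[2])
  flips <- config@allowFlips & (runif(2) < 0.5)
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  Sh <- matrix(c(1, shear, 0, 1), 2, 2)
  F <- diag(ifelse(flips, -1, 1))
  M <- R %*% Sh %*% (zoom * F)
  identityTf <- identical(unname(M), diag(2)) && all(shift == 0)
  list(M = M, shift = shift, identity = identityTf)
}

## EBImage::affine maps row-vector points p to p %*% A + b; we want content
## transformed by M about the image center c plus a translation:
## p' = (p - c) M^T + c + shift.
.affineParams <- function(M, shift, side) {
  A <- t(M)
  cc <- matrix(c((side + 1) / 2, (side + 1) / 2), 1, 2)
  b <- cc + matrix(shift, 1, 2) - cc %*% A
  rbind(A, as.numeric(b))
}

.warpPlane <- function(plane, m, filter, bg) {
  EBImage::imageData(EBImage::affine(EBImage::Image(plane), m, filter = filter, bg.col = bg))
}

#' Randomly transform one labeled example
#'
#' Draws one transform (rotation, shift, shear, zoom, flips) from the config
#' and applies it identically to the image and every attached mask: bilinear
#' interpolation for the image, nearest-neighbor for masks so they stay
#' strictly binary and their nesting (nucleus in cell, vacuoles in cytoplasm)
#' is preserved exactly. Out-of-frame regions are filled with the image's
#' border median color (the background stain); masks are filled with
#' background. The label is preserved.
#'
#' @param image a \linkS4class{CellImage}.
#' @param config an \linkS4class{AugmentationConfig}.
#' @param seed integer; the same image, config and seed give identical output.
#' @return a transformed \linkS4class{CellImage}.
#' @export
setMethod("augmentExample", signature("CellImage", "AugmentationConfig"),
          function(image, config, seed) {
  tf <- withSeed(seed, .sampleTransform(config, dim(image@pixels)[1]))
  if (tf$identity) return(image)
  side <- dim(image@pixels)[1]
  m <- .affineParams(tf$M, tf$shift, side)
  px <- image@pixels
  for (ch in 1:3) {
    plane <- image@pixels[, , ch]
    bg <- stats::median(c(plane[1, ], plane[side, ], plane[, 1], plane[, side]))
    px[, , ch] <- .warpPlane(plane, m, "bilinear", bg)
  }
  px <- clamp01(px)
  warpMask <- function(mk) {
    if (is.null(mk)) return(NULL)
    binaryMask(.warpPlane(mk@grid * 1, m, "none", 0) > 0.5)
  }
  cellImage(px, cellMask = warpMask(image@cellMask),
            nucleusMask = warpMask(image@nucleusMask),
            vacuoleMask = warpMask(image@vacuoleMask),
            label = image@label, subjectId = image@subjectId)
})

#' Expand a dataset by a fixed multiplicative factor
#'
#' Produces exactly \code{factor} transformed copies of every input example
#' (the augmented set replaces the originals; the identity transform can
#' occur by chance). Output order groups copies by source image and names
#' each output \code{<source index>_aug<copy>} so every example is traceable
#' to its source.
#'
#' @param images nonempty list of \linkS4class{CellImage}.
#' @param config an \linkS4class{AugmentationConfig}.
#' @return list of length \code{length(images) * factor}.
#' @examples
#' # 401 originals at factor 20 give 8020 training examples
#' @export
augmentDataset <- function(images, config = augmentationConfig()) {
  if (length(images) == 0L) vqError("input list must be nonempty", "vq_parameter_error")
  out <- vector("list", length(images) * config@factor)
  nms <- character(length(out))
  k <- 0L
  for (i in seq_along(images)) {
    for (j in seq_len(config@factor)) {
      k <- k + 1L
      out[[k]] <- augmentExample(images[[i]], config, deriveSeed(config@seed, k))
      nms[k] <- sprintf("%d_aug%d", i, j)
    }
  }
  names(out) <- nms
  out
}
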