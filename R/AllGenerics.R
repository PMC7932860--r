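#' @include AllClasses.R
NULL

#' @rdname dice
#' @export
setGeneric("dice", function(a, b) standardGeneric("dice"))

#' @rdname cytoplasmMask
#' @export
setGeneric("cytoplasmMask", function(cell, nucleus) standardGeneric("cytoplasmMask"))

#' @rdname applyMask
#' @export
setGeneric("applyMask", function(image, mask) standardGeneric("applyMask"))

#' @rdname generateCell
#' @export
setGeneric("generateCell", function(params, vacuolated, seed) standardGeneric("generateCell"))

#' @rdname augmentExample
#' @export
setGeneric("augmentExample", function(image, config, seed) standardGeneric("augmentExample"))

#' @rdname isVacuolated
#' @export
setGeneric("isVacuolated", function(p, threshold) standardGeneric("isVacuolated"))

## ---- accessors ----

#' Mask accessors
#'
#' @param x a \linkS4class{BinaryMask}
#' @return \code{maskGrid} returns the logical matrix; \code{nForeground} the
#'   number of foreground pixels.
#' @export
maskGrid <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@grid
}

#' @rdname maskGrid
#' @export
nForeground <- function(x) sum(maskGrid(x))

#' CellImage accessors
#'
#' @param x a \linkS4class{CellImage}
#' @return pixel array, masks, or label.
#' @export
cellPixels <- function(x) x@pixels

#' @rdname cellPixels
#' @export
cellMask <- function(x) x@cellMask

#' @rdname cellPixels
#' @export
nucleusMask <- function(x) x@nucleusMask

#' @rdname cellPixels
#' @export
vacuoleMask <- function(x) x@vacuoleMask

#' @rdname cellPixels
#' @export
cellLabel <- function(x) x@label

#' Score and model accessors
#'
#' @param x a result object
#' @return the underlying numeric summary.
#' @export
diceValue <- function(x) x@value

#' @rdname diceValue
#' @export
validationDice <- function(x) x@validationDice

#' @rdname diceValue
#' @export
validationAccuracy <- function(x) x@validationAccuracy

#' @rdname diceValue
#' @export
trainingHistory <- function(x) x@history

#' @rdname diceValue
#' @export
percentVacuolated <- function(x) x@percentVacuolated

#' @rdname diceValue
#' @export
perCellResults <- function(x) x@perCell

## ---- show methods ----

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("BinaryMask %d x %d, %d foreground pixels\n", d[1], d[2], sum(object@grid)))
})

setMethod("show", "CellImage", function(object) {
  d <- dim(object@pixels)
  masks <- c(cell = !is.null(object@cellMask), nucleus = !is.null(object@nucleusMask),
             vacuole = !is.null(object@vacuoleMask))
  cat(sprintf("CellImage %d x %d RGB, label: %s, masks: %s\n", d[1], d[2],
              ifelse(is.na(object@label), "<none>", object@label),
              if (any(masks)) paste(names(masks)[masks], collapse = "+") else "<none>"))
})

setMethod("show", "DiceScore", function(object) {
  cat(sprintf("DiceScore %.4f (overlap %d, total foreground %d)\n",
              object@value, object@overlapPixels, object@totalPixels))
})

setMethod("show", "SegModelBundle", function(object) {
  cat(sprintf("SegModelBundle target=%s, depth %d x %d filters, validation dice %.4f\n",
              object@config@target, object@config@depth, object@config@baseFilters,
              object@validationDice))
})

setMethod("show", "ClsModelBundle", function(object) {
  cat(sprintf("ClsModelBundle %d-stage residual classifier, validation accuracy %.4f\n",
              3L, object@validationAccuracy))
})

setMethod("show", "VacuolizationResult", function(object) {
  cat(sprintf("VacuolizationResult smear %s: %d cells (%d excluded), %d vacuolated = %.1f%%\n",
              object@smearId, object@nCellsTotal, object@nCellsExcluded,
              object@nVacuolated, object@percentVacuolated))
})

setMethod("show", "PassingBablokFit", function(object) {
  cat(sprintf("Passing-Bablok fit: slope %.3f (95%% CI %.3f-%.3f), intercept %.3f (95%% CI %.3f-%.3f)\n",
              object@slope, object@slopeCI[1], object@slopeCI[2],
              object@intercept, object@interceptCI[1], object@interceptCI[2]))
  cat(sprintf("  %d pairwise slopes, %d bootstrap samples\n",
              object@nPairwiseSlopes, object@bootstrapSamples))
})

setMethod("show", "BlandAltmanResult", function(object) {
  cat(sprintf("Bland-Altman: mean difference %.3f, SD %.3f, LoA [%.3f, %.3f], n = %d\n",
              object@meanDifference, object@sdDifference, object@loa[1], object@loa[2], object@n))
})

setMethod("show", "LeveneResult", function(object) {
  cat(sprintf("Levene's test: W = %.4f, df = (%d, %d), p = %.4f\n",
              object@W, object@dfBetween, object@dfWithin, object@pValue))
})

setMethod("show", "MethodComparisonResult", function(object) {
  cat("Method comparison report\n")
  if (!is.null(object@passingBablok)) show(object@passingBablok)
  cat(sprintf("  Pearson r = %s\n", ifelse(is.na(object@pearson), "NA (degenerate)",
                                           sprintf("%.4f", object@pearson))))
  if (!is.null(object@levene)) show(object@levene)
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
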