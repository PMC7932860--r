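#' @import methods
NULL

## Structured conditions so callers can distinguish failure modes
## (shape vs parameter vs degenerate data vs segmentation failure ...).
vqError <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "vq_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.isRange <- function(x) is.numeric(x) && length(x) == 2L && !anyNA(x) && x[1] <= x[2]

#' Binary mask aligned to an image
#'
#' A strictly two-valued 2-D field. The grid is a logical matrix with the same
#' orientation as image pixel arrays: row-major, origin at the top-left corner
#' (row 1, column 1 in R's 1-based indexing).
#'
#' @slot grid logical matrix; \code{TRUE} marks foreground.
#' @export
setClass("BinaryMask", slots = c(grid = "matrix"), validity = function(object) {
  g <- object@grid
  if (!is.logical(g)) return("grid must be a logical matrix")
  if (anyNA(g)) return("grid must not contain NA")
  if (nrow(g) < 1L || ncol(g) < 1L) return("grid dimensions must be positive")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param grid a logical or numeric matrix; numeric input is interpreted as
#'   foreground where the value exceeds 0.5 (the convention used when masks
#'   round-trip through 8-bit grayscale PNG).
#' @return a \linkS4class{BinaryMask}
#' @examples
#' m <- binaryMask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' nForeground(m)
#' @export
binaryMask <- function(grid) {
  if (is.numeric(grid)) grid <- grid > 0.5
  new("BinaryMask", grid = grid)
}

#' Single-cell image with optional ground-truth masks
#'
#' An RGB crop of one centered leukocyte, as produced by digital morphology
#' analyzers, with intensities in [0, 1]. Ground-truth cell, nucleus and
#' vacuole masks may be attached; when present they must be spatially aligned
#' and nested: nucleus inside cell, vacuoles inside the cytoplasm
#' (cell minus nucleus).
#'
#' @slot pixels numeric array height x width x 3, values in [0, 1].
#' @slot cellMask,nucleusMask,vacuoleMask \linkS4class{BinaryMask} or NULL.
#' @slot label "vacuolated", "healthy", or NA when unlabeled.
#' @slot subjectId free-text subject/smear identifier (NA when unset).
#' @export
setClass("CellImage",
  slots = c(pixels = "array", cellMask = "ANY", nucleusMask = "ANY",
            vacuoleMask = "ANY", label = "character", subjectId = "character"),
  prototype = prototype(cellMask = NULL, nucleusMask = NULL, vacuoleMask = NULL,
                        label = NA_character_, subjectId = NA_character_),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("pixels must be a height x width x 3 array")
    if (anyNA(p) || min(p) < 0 || max(p) > 1)
      return("pixel intensities must lie in [0, 1]")
    hw <- dim(p)[1:2]
    for (nm in c("cellMask", "nucleusMask", "vacuoleMask")) {
      m <- slot(object, nm)
      if (is.null(m)) next
      if (!is(m, "BinaryMask")) return(sprintf("%s must be a BinaryMask or NULL", nm))
      if (!identical(dim(m@grid), as.integer(hw)))
        return(sprintf("%s dimensions do not match the pixel field", nm))
    }
    cm <- object@cellMask; nm <- object@nucleusMask; vm <- object@vacuoleMask
    if (!is.null(cm) && !is.null(nm) && any(nm@grid & !cm@grid))
      return("nucleus mask extends outside the cell mask")
    if (!is.null(vm) && !is.null(cm) && !is.null(nm) &&
        any(vm@grid & !(cm@grid & !nm@grid)))
      return("vacuole mask extends outside the cytoplasm (cell minus nucleus)")
    if (!is.na(object@label) && !object@label %in% c("vacuolated", "healthy"))
      return("label must be 'vacuolated', 'healthy', or NA")
    TRUE
  })

#' Construct a CellImage
#'
#' @param pixels height x width x 3 numeric array in [0, 1]
#' @param cellMask,nucleusMask,vacuoleMask optional \linkS4class{BinaryMask}
#' @param label optional "vacuolated" or "healthy"
#' @param subjectId optional identifier
#' @return a \linkS4class{CellImage}
#' @export
cellImage <- function(pixels, cellMask = NULL, nucleusMask = NULL,
                      vacuoleMask = NULL, label = NA_character_,
                      subjectId = NA_character_) {
  new("CellImage", pixels = pixels, cellMask = cellMask, nucleusMask = nucleusMask,
      vacuoleMask = vacuoleMask, label = label, subjectId = subjectId)
}

#' Generative parameters for synthetic stained-lymphocyte crops
#'
#' Describes the geometry and coloring of a synthetic May-Grünwald-Giemsa
#' stained lymphocyte: a roughly circular cell on a pale background, a large
#' dark nucleus, a thin cytoplasm rim, and (in vacuolated cells) round pale
#' clearings confined to the cytoplasm.
#'
#' @slot imageSize pixels per side of the square crop.
#' @slot cellRadiusRange min/max cell radius in pixels.
#' @slot nucleusAreaFractionRange min/max fraction of cell area the nucleus occupies.
#' @slot vacuoleCountRange integer min/max vacuoles per vacuolated cell (min >= 1).
#' @slot vacuoleRadiusRange min/max vacuole radius in pixels.
#' @slot boundaryIrregularity dimensionless amplitude of the radial boundary perturbation.
#' @slot stainPalette named list of mean RGB triplets: background, cytoplasm,
#'   nucleus, vacuole.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot clutterCount distractor discs drawn on the background outside the
#'   cell (0 = clean background); used to probe the value of cytoplasm
#'   masking before classification.
#' @slot seed integer base seed; identical parameters including the seed
#'   reproduce bit-identical images.
#' @export
setClass("SyntheticParams",
  slots = c(imageSize = "integer", cellRadiusRange = "numeric",
            nucleusAreaFractionRange = "numeric", vacuoleCountRange = "integer",
            vacuoleRadiusRange = "numeric", boundaryIrregularity = "numeric",
            stainPalette = "list", noiseSd = "numeric", clutterCount = "integer",
            seed = "integer"),
  validity = function(object) {
    if (object@imageSize < 16L) return("imageSize must be at least 16 pixels")
    for (nm in c("cellRadiusRange", "nucleusAreaFractionRange", "vacuoleRadiusRange"))
      if (!.isRange(slot(object, nm))) return(sprintf("%s must be a valid min/max pair", nm))
    if (any(object@nucleusAreaFractionRange <= 0) || any(object@nucleusAreaFractionRange >= 1))
      return("nucleusAreaFractionRange must lie strictly inside (0, 1)")
    if (object@vacuoleCountRange[1] < 1L) return("vacuoleCountRange minimum must be >= 1")
    if (object@vacuoleCountRange[1] > object@vacuoleCountRange[2])
      return("vacuoleCountRange must be ordered")
    maxReach <- object@cellRadiusRange[2] * (1 + object@boundaryIrregularity)
    if (maxReach >= object@imageSize / 2)
      return("cell does not fit: max radius plus perturbation must be < imageSize/2")
    pal <- object@stainPalette
    need <- c("background", "cytoplasm", "nucleus", "vacuole")
    if (!all(need %in% names(pal))) return("stainPalette must name background/cytoplasm/nucleus/vacuole")
    for (nm in need) {
      v <- pal[[nm]]
      if (!is.numeric(v) || length(v) != 3L || any(v < 0) || any(v > 1))
        return(sprintf("stainPalette$%s must be an RGB triplet in [0,1]", nm))
    }
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    if (object@clutterCount < 0L) return("clutterCount must be non-negative")
    TRUE
  })

#' Geometric augmentation configuration
#'
#' The five transform families (rotation, shifting, shearing, zooming,
#' flipping) with their magnitude ranges, and the multiplicative expansion
#' factor: each input example yields \code{factor} transformed copies.
#'
#' @slot factor integer multiplier (>= 1).
#' @slot rotationMaxDeg rotation drawn uniformly in +/- this many degrees.
#' @slot shiftMaxFraction translation per axis, as a fraction of the image side.
#' @slot shearMaxDeg shear angle drawn uniformly in +/- this many degrees.
#' @slot zoomRange min/max isotropic scale factor.
#' @slot allowFlips logical length-2 (horizontal, vertical).
#' @slot seed integer.
#' @export
setClass("AugmentationConfig",
  slots = c(factor = "integer", rotationMaxDeg = "numeric", shiftMaxFraction = "numeric",
            shearMaxDeg = "numeric", zoomRange = "numeric", allowFlips = "logical",
            seed = "integer"),
  validity = function(object) {
    if (object@factor < 1L) return("factor must be >= 1")
    if (!.isRange(object@zoomRange) || any(object@zoomRange <= 0))
      return("zoomRange must be an ordered positive pair")
    if (length(object@allowFlips) != 2L || anyNA(object@allowFlips))
      return("allowFlips must be c(horizontal, vertical)")
    if (object@rotationMaxDeg < 0 || object@shiftMaxFraction < 0 || object@shearMaxDeg < 0)
      return("transform magnitudes must be non-negative")
    TRUE
  })

#' Dice similarity score between two binary masks
#'
#' value = 2 * overlapPixels / totalPixels, where totalPixels is the summed
#' foreground of both masks; 0 means no spatial overlap, 1 complete overlap.
#'
#' @slot value dimensionless, in [0, 1].
#' @slot overlapPixels,totalPixels pixel counts.
#' @export
setClass("DiceScore",
  slots = c(value = "numeric", overlapPixels = "integer", totalPixels = "integer"),
  validity = function(object) {
    if (object@totalPixels <= 0L) return("totalPixels must be positive")
    expect <- 2 * object@overlapPixels / object@totalPixels
    if (abs(object@value - expect) > 1e-12) return("value inconsistent with pixel counts")
    if (object@value < 0 || object@value > 1) return("value must lie in [0, 1]")
    TRUE
  })

#' Segmentation training configuration
#'
#' @slot target "cell" or "nucleus" — which ground-truth mask the model learns.
#' @slot splitFraction training proportion of the 80/20-style split.
#' @slot epochs,batchSize,learningRate optimizer settings (Adam).
#' @slot binarizationThreshold probability cut turning the sigmoid map into a mask.
#' @slot depth number of encoder levels of the U-Net; \code{baseFilters}
#'   channels at the top level, doubling per level.
#' @slot seed integer controlling init, split and batch order.
#' @export
setClass("SegTrainConfig",
  slots = c(target = "character", splitFraction = "numeric", epochs = "integer",
            batchSize = "integer", learningRate = "numeric",
            binarizationThreshold = "numeric", depth = "integer",
            baseFilters = "integer", seed = "integer"),
  validity = function(object) {
    if (!object@target %in% c("cell", "nucleus")) return("target must be 'cell' or 'nucleus'")
    if (object@splitFraction <= 0 || object@splitFraction >= 1)
      return("splitFraction must lie in (0, 1)")
    if (object@binarizationThreshold <= 0 || object@binarizationThreshold >= 1)
      return("binarizationThreshold must lie in (0, 1)")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@depth < 1L || object@baseFilters < 1L) return("architecture knobs must be >= 1")
    TRUE
  })

#' Trained segmentation model with its validation record
#'
#' @slot weights named list of parameter arrays.
#' @slot config the \linkS4class{SegTrainConfig} used.
#' @slot validationDice mean dice over the validation split for the declared target.
#' @slot history data.frame with per-epoch loss and validation dice.
#' @export
setClass("SegModelBundle",
  slots = c(weights = "list", config = "SegTrainConfig",
            validationDice = "numeric", history = "data.frame"))

#' Classifier training configuration
#'
#' @slot splitFraction training proportion.
#' @slot epochs,batchSize,learningRate optimizer settings (Adam); the best
#'   validation-accuracy epoch is checkpointed.
#' @slot baseFilters channels of the first residual stage (doubling per stage).
#' @slot blocksPerStage residual blocks in each of the three stages.
#' @slot seed integer.
#' @export
setClass("ClsTrainConfig",
  slots = c(splitFraction = "numeric", epochs = "integer", batchSize = "integer",
            learningRate = "numeric", baseFilters = "integer",
            blocksPerStage = "integer", seed = "integer"),
  validity = function(object) {
    if (object@splitFraction <= 0 || object@splitFraction >= 1)
      return("splitFraction must lie in (0, 1)")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@baseFilters < 1L || object@blocksPerStage < 1L)
      return("architecture knobs must be >= 1")
    TRUE
  })

#' Trained vacuolization classifier
#'
#' @slot weights named list of parameter arrays.
#' @slot config the \linkS4class{ClsTrainConfig} used.
#' @slot validationAccuracy proportion correct on the validation split at the
#'   checkpointed epoch.
#' @slot history per-epoch loss and validation accuracy.
#' @export
setClass("ClsModelBundle",
  slots = c(weights = "list", config = "ClsTrainConfig",
            validationAccuracy = "numeric", history = "data.frame"))

#' Softmax class-probability vector
#'
#' The classifier's output: the probability of the cell being a vacuolated
#' lymphocyte and its complement. The two entries sum to 1 (softmax).
#'
#' @slot pVacuolated,pHealthy probabilities in [0, 1] summing to 1.
#' @export
setClass("ProbabilityVector",
  slots = c(pVacuolated = "numeric", pHealthy = "numeric"),
  validity = function(object) {
    p <- c(object@pVacuolated, object@pHealthy)
    if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-6) return("probabilities must sum to 1")
    TRUE
  })

#' @rdname ProbabilityVector-class
#' @param pVacuolated probability of the vacuolated class
#' @export
probabilityVector <- function(pVacuolated) {
  new("ProbabilityVector", pVacuolated = pVacuolated, pHealthy = 1 - pVacuolated)
}

#' Probability threshold for the vacuolization decision
#'
#' A cell is called vacuolated when its softmax probability of the vacuolated
#' class is greater than or equal to tau (inclusive).
#'
#' @slot tau probability in (0, 1); default 0.65.
#' @export
setClass("DecisionThreshold", slots = c(tau = "numeric"), validity = function(object) {
  if (length(object@tau) != 1L || is.na(object@tau) || object@tau <= 0 || object@tau >= 1)
    return("tau must be a single probability strictly inside (0, 1)")
  TRUE
})

#' @rdname DecisionThreshold-class
#' @param tau probability in (0, 1)
#' @export
decisionThreshold <- function(tau = 0.65) new("DecisionThreshold", tau = tau)

#' Grad-CAM attribution heatmap
#'
#' @slot heatmap matrix in [0, 1], upsampled to the input image dimensions;
#'   normalized so the maximum is 1 unless the raw map is identically zero.
#' @slot targetClass the class whose score was attributed.
#' @export
setClass("GradCamMap",
  slots = c(heatmap = "matrix", targetClass = "character"),
  validity = function(object) {
    h <- object@heatmap
    if (anyNA(h) || min(h) < 0 || max(h) > 1) return("heatmap values must lie in [0, 1]")
    if (max(h) > 0 && abs(max(h) - 1) > 1e-9)
      return("nonzero heatmap must be normalized to max 1")
    TRUE
  })

#' Per-smear vacuolization quantification
#'
#' @slot smearId identifier.
#' @slot nCellsTotal cells submitted.
#' @slot nCellsExcluded segmentation failures (no usable cytoplasm mask);
#'   excluded from the percentage denominator and reported.
#' @slot nVacuolated cells whose decision was positive.
#' @slot percentVacuolated 100 * nVacuolated / (nCellsTotal - nCellsExcluded).
#' @slot perCell data.frame: cell_id, p_vacuolated, decision, excluded.
#' @export
setClass("VacuolizationResult",
  slots = c(smearId = "character", nCellsTotal = "integer", nCellsExcluded = "integer",
            nVacuolated = "integer", percentVacuolated = "numeric", perCell = "data.frame"),
  validity = function(object) {
    if (object@percentVacuolated < 0 || object@percentVacuolated > 100)
      return("percentVacuolated must lie in [0, 100]")
    pc <- object@perCell
    if (!all(c("cell_id", "p_vacuolated", "decision", "excluded") %in% names(pc)))
      return("perCell must have columns cell_id, p_vacuolated, decision, excluded")
    if (sum(pc$decision & !pc$excluded) != object@nVacuolated)
      return("nVacuolated inconsistent with per-cell decisions")
    if (nrow(pc) != object@nCellsTotal) return("nCellsTotal inconsistent with perCell")
    if (sum(pc$excluded) != object@nCellsExcluded)
      return("nCellsExcluded inconsistent with perCell")
    TRUE
  })

#' Paired per-smear measurements from two quantification methods
#'
#' @slot x,y equal-length numeric vectors (method A, method B).
#' @export
setClass("PairedMeasurements", slots = c(x = "numeric", y = "numeric"),
  validity = function(object) {
    if (length(object@x) != length(object@y)) return("x and y must have equal length")
    if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
      return("values must be finite")
    TRUE
  })

#' @rdname PairedMeasurements-class
#' @param x,y equal-length numeric vectors
#' @export
pairedMeasurements <- function(x, y) new("PairedMeasurements", x = as.numeric(x), y = as.numeric(y))

#' Passing-Bablok regression fit
#'
#' Nonparametric method-comparison regression: the slope is the shifted median
#' of all pairwise slopes, robust to measurement error in both methods;
#' confidence intervals come from bootstrap resampling of the pairs.
#'
#' @slot slope,intercept point estimates.
#' @slot slopeCI,interceptCI 95% percentile bootstrap intervals (low, high).
#' @slot nPairwiseSlopes number of valid pairwise slopes used.
#' @slot bootstrapSamples number of bootstrap resamples.
#' @slot seed bootstrap seed.
#' @export
setClass("PassingBablokFit",
  slots = c(slope = "numeric", intercept = "numeric", slopeCI = "numeric",
            interceptCI = "numeric", nPairwiseSlopes = "integer",
            bootstrapSamples = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@slopeCI) != 2L || length(object@interceptCI) != 2L)
      return("CIs must be length-2 (low, high)")
    if (object@slope < object@slopeCI[1] - 1e-9 || object@slope > object@slopeCI[2] + 1e-9)
      return("slope must lie within its CI")
    if (object@intercept < object@interceptCI[1] - 1e-9 ||
        object@intercept > object@interceptCI[2] + 1e-9)
      return("intercept must lie within its CI")
    TRUE
  })

#' Bland-Altman agreement statistics
#'
#' @slot meanDifference mean of paired differences x - y.
#' @slot sdDifference sample standard deviation (n - 1 denominator).
#' @slot loa limits of agreement, mean +/- 1.96 sd.
#' @slot n number of pairs.
#' @export
setClass("BlandAltmanResult",
  slots = c(meanDifference = "numeric", sdDifference = "numeric",
            loa = "numeric", n = "integer"),
  validity = function(object) {
    if (length(object@loa) != 2L) return("loa must be length-2")
    if (object@loa[1] > object@meanDifference + 1e-12 ||
        object@loa[2] < object@meanDifference - 1e-12)
      return("mean difference must lie inside the limits of agreement")
    TRUE
  })

#' Levene variance-homogeneity test result
#'
#' Classic Levene W on absolute deviations from each group's mean, referred to
#' the F distribution with (k - 1, N - k) degrees of freedom.
#'
#' @slot W test statistic (>= 0).
#' @slot dfBetween,dfWithin degrees of freedom.
#' @slot pValue in [0, 1].
#' @slot groupLabels group names in input order.
#' @export
setClass("LeveneResult",
  slots = c(W = "numeric", dfBetween = "integer", dfWithin = "integer",
            pValue = "numeric", groupLabels = "character"),
  validity = function(object) {
    if (object@W < 0) return("W must be non-negative")
    if (object@pValue < 0 || object@pValue > 1) return("pValue must lie in [0, 1]")
    if (object@dfBetween != length(object@groupLabels) - 1L)
      return("dfBetween must equal number of groups minus 1")
    TRUE
  })

#' Full method-comparison report
#'
#' Bundles the comparison of an automated quantification against the consensus
#' (mean) of two manual quantifications: Passing-Bablok fit, Bland-Altman for
#' auto vs consensus and for the two manual raters, Pearson correlation, and
#' Levene's test on the three paired-difference groups
#' (auto - manual1, auto - manual2, manual1 - manual2).
#'
#' Degenerate sub-analyses (constant inputs, zero deviations) are replaced by
#' NULL/NA and recorded in \code{flags} rather than raising, so a full-
#' agreement comparison still yields a report.
#'
#' @slot passingBablok \linkS4class{PassingBablokFit} or NULL.
#' @slot blandAltmanAuto,blandAltmanManual \linkS4class{BlandAltmanResult} or NULL.
#' @slot pearson numeric (NA when degenerate).
#' @slot levene \linkS4class{LeveneResult} or NULL.
#' @slot flags character vector naming degenerate sub-analyses.
#' @export
setClass("MethodComparisonResult",
  slots = c(passingBablok = "ANY", blandAltmanAuto = "ANY", blandAltmanManual = "ANY",
            pearson = "numeric", levene = "ANY", flags = "character"))

#' End-to-end workflow configuration
#'
#' @slot outDir root directory for artifacts.
#' @slot synth \linkS4class{SyntheticParams}.
#' @slot nSmears,cellsPerSmear,fractions synthetic dataset shape.
#' @slot augment \linkS4class{AugmentationConfig}.
#' @slot segCell,segNucleus \linkS4class{SegTrainConfig}.
#' @slot cls \linkS4class{ClsTrainConfig}.
#' @slot threshold \linkS4class{DecisionThreshold}.
#' @slot nSegCells,nClsCells training-set sizes for the two stages.
#' @slot bootstrapSamples bootstrap resamples for Passing-Bablok.
#' @slot raterNoiseSd SD (percentage points) of the simulated manual raters.
#' @slot seed global seed from which all stage seeds derive.
#' @export
setClass("PipelineConfig",
  slots = c(outDir = "character", synth = "SyntheticParams", nSmears = "integer",
            cellsPerSmear = "integer", fractions = "numeric",
            augment = "AugmentationConfig", segCell = "SegTrainConfig",
            segNucleus = "SegTrainConfig", cls = "ClsTrainConfig",
            threshold = "DecisionThreshold", nSegCells = "integer",
            nClsCells = "integer", bootstrapSamples = "integer",
            raterNoiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@fractions) != object@nSmears)
      return("fractions must have one entry per smear")
    if (any(object@fractions < 0) || any(object@fractions > 1))
      return("fractions must lie in [0, 1]")
    if (object@nSmears < 1L || object@cellsPerSmear < 1L)
      return("dataset shape must be positive")
    if (object@raterNoiseSd < 0) return("raterNoiseSd must be non-negative")
    TRUE
  })
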