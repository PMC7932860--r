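#' @include AllClasses.R AllGenerics.R utils.R nn-core.R unet.R mask-ops.R augment.R
NULL

#' Construct a segmentation training configuration
#'
#' @param target which ground-truth mask to learn: "cell" or "nucleus".
#' @param splitFraction training proportion; default 0.8 (an 80/20 split).
#' @param epochs training epochs; default 10. The boundary accuracy of the
#'   cytoplasm mask keeps improving for a few epochs after the dice score
#'   plateaus to the second decimal, and the classifier downstream is
#'   sensitive to clipped vacuoles, so the default trains past the plateau.
#' @param batchSize minibatch size; default 8.
#' @param learningRate Adam step size; default 1e-3.
#' @param binarizationThreshold probability cut for mask foreground; default 0.5.
#' @param depth encoder levels; default 3.
#' @param baseFilters channels at the top level (doubling per level); default 16.
#' @param seed controls weight init, the split, and batch order.
#' @return a \linkS4class{SegTrainConfig}.
#' @export
segTrainConfig <- function(target = c("cell", "nucleus"), splitFraction = 0.8,
                           epochs = 10L, batchSize = 8L, learningRate = 1e-3,
                           binarizationThreshold = 0.5, depth = 3L,
                           baseFilters = 16L, seed = 1L) {
  target <- match.arg(target)
  tryCatch(
    new("SegTrainConfig", target = target, splitFraction = splitFraction,
        epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        learningRate = learningRate, binarizationThreshold = binarizationThreshold,
        depth = as.integer(depth), baseFilters = as.integer(baseFilters),
        seed = as.integer(seed)),
    error = function(e) vqError(conditionMessage(e), "vq_parameter_error"))
}

#' Deterministic train/validation split
#'
#' Training portion has floor(n * splitFraction) elements; the remainder is
#' the validation set. The permutation is reproducible from the seed and the
#' two parts are disjoint.
#'
#' @param examples a list.
#' @param splitFraction proportion in (0, 1); default 0.8.
#' @param seed integer.
#' @return list with \code{train} and \code{validation} lists.
#' @examples
#' sp <- splitDataset(as.list(1:100), 0.8, seed = 1)
#' lengths(sp)  # 80 and 20
#' @export
splitDataset <- function(examples, splitFraction = 0.8, seed = 1L) {
  n <- length(examples)
  if (n < 2L) vqError("need at least 2 examples to split", "vq_parameter_error")
  if (splitFraction <= 0 || splitFraction >= 1)
    vqError("splitFraction must lie in (0, 1)", "vq_parameter_error")
  nTrain <- floor(n * splitFraction)
  if (nTrain < 1L || nTrain >= n)
    vqError("split leaves an empty partition", "vq_parameter_error")
  perm <- withSeed(seed, sample.int(n))
  list(train = examples[perm[seq_len(nTrain)]],
       validation = examples[perm[(nTrain + 1L):n]])
}

.targetMask <- function(image, target) {
  m <- if (target == "cell") image@cellMask else image@nucleusMask
  if (is.null(m))
    vqError(sprintf("example lacks the ground-truth %s mask", target), "vq_data_error")
  m
}

## hard dice between a prediction grid and ground truth, safe for empty pairs
.hardDice <- function(pred, truth) {
  tot <- sum(pred) + sum(truth)
  if (tot == 0L) return(1)
  2 * sum(pred & truth) / tot
}

.meanValDice <- function(params, depth, Xval, valMasks, thr, chunk = 8L) {
  nval <- dim(Xval)[3]
  vals <- numeric(nval)
  for (start in seq(1L, nval, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nval)
    fw <- unetForward(params, Xval[, , idx, , drop = FALSE], depth, keepCache = FALSE)
    for (j in seq_along(idx)) {
      pred <- fw$prob[, , j, 1] >= thr
      vals[idx[j]] <- .hardDice(pred, valMasks[[idx[j]]]@grid)
    }
  }
  mean(vals)
}

#' Train the cell- or nucleus-mask segmentation model
#'
#' Fits the U-Net style segmenter with Adam on a soft dice loss (1 minus the
#' differentiable dice of the predicted probability map against the
#' ground-truth mask), after an internal train/validation split. The recorded
#' validation dice is the mean hard dice (maps binarized at the configured
#' threshold) over the validation images, for the declared target only.
#'
#' @param examples list of \linkS4class{CellImage}, each carrying the
#'   ground-truth mask for the configured target.
#' @param config a \linkS4class{SegTrainConfig}.
#' @param augment optional \linkS4class{AugmentationConfig}; when given, the
#'   training portion (only) is expanded by the augmentation factor after the
#'   split, so no transformed copy of a validation image leaks into training.
#' @param quiet suppress per-epoch progress; default TRUE.
#' @return a \linkS4class{SegModelBundle}.
#' @export
trainSegmenter <- function(examples, config = segTrainConfig(), augment = NULL,
                           quiet = TRUE) {
  if (!is(config, "SegTrainConfig")) vqError("config must be a SegTrainConfig", "vq_parameter_error")
  masks <- lapply(examples, .targetMask, target = config@target)
  sp <- splitDataset(seq_along(examples), config@splitFraction, config@seed)
  trIdx <- unlist(sp$train); vaIdx <- unlist(sp$validation)
  trainEx <- examples[trIdx]
  if (!is.null(augment)) trainEx <- augmentDataset(trainEx, augment)
  Xtr <- nnStackImages(trainEx)
  Ttr <- nnStackMasks(lapply(trainEx, .targetMask, target = config@target))
  Xva <- nnStackImages(examples[vaIdx])
  side <- dim(Xtr)[1]
  if (side %% 2L^(config@depth - 1L) != 0L)
    vqError("image side must be divisible by 2^(depth-1)", "vq_shape_error")

  params <- withSeed(config@seed, unetInit(config@depth, config@baseFilters))
  state <- adamInit(params)
  nTrain <- dim(Xtr)[3]
  history <- data.frame(epoch = integer(), loss = numeric(), val_dice = numeric())
  withSeed(deriveSeed(config@seed, 17L), {
    for (ep in seq_len(config@epochs)) {
      ord <- sample.int(nTrain)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, nTrain, by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, nTrain)]
        fw <- unetForward(params, Xtr[, , idx, , drop = FALSE], config@depth)
        ls <- softDiceLoss(fw$prob, Ttr[, , idx, , drop = FALSE])
        if (!is.finite(ls$loss)) vqError("non-finite training loss", "vq_model_error")
        gr <- unetBackward(params, ls$dLogit, fw$cache, config@depth)
        up <- adamStep(params, gr, state, config@learningRate)
        params <- up$params; state <- up$state
        epLoss <- epLoss + ls$loss; nb <- nb + 1L
      }
      vd <- .meanValDice(params, config@depth, Xva, masks[vaIdx], config@binarizationThreshold)
      history <- rbind(history, data.frame(epoch = ep, loss = epLoss / nb, val_dice = vd))
      if (!quiet) message(sprintf("[%s] epoch %d  loss %.4f  val dice %.4f",
                                  config@target, ep, epLoss / nb, vd))
    }
  })
  new("SegModelBundle", weights = params, config = config,
      validationDice = history$val_dice[nrow(history)], history = history)
}

#' Predict a binary mask for one cell image
#'
#' Runs the trained segmenter and thresholds the sigmoid probability map at
#' the bundle's binarization threshold. Output dimensions equal input
#' dimensions.
#'
#' @param bundle a trained \linkS4class{SegModelBundle}.
#' @param image a \linkS4class{CellImage}.
#' @return a \linkS4class{BinaryMask}.
#' @export
predictMask <- function(bundle, image) {
  if (!is(bundle, "SegModelBundle")) vqError("bundle must be a SegModelBundle", "vq_model_error")
  d <- dim(image@pixels)
  if (d[1] %% 2L^(bundle@config@depth - 1L) != 0L ||
      d[2] %% 2L^(bundle@config@depth - 1L) != 0L)
    vqError("image dimensions incompatible with the model's pooling depth", "vq_shape_error")
  X <- array(image@pixels, c(d[1], d[2], 1L, 3L))
  fw <- unetForward(bundle@weights, X, bundle@config@depth, keepCache = FALSE)
  binaryMask(fw$prob[, , 1, 1] >= bundle@config@binarizationThreshold)
}

#' Segment the cytoplasm and black out everything else
#'
#' The deployed two-model segmentation step: predict the cell mask and the
#' nucleus mask, form the cytoplasm mask by subtraction, and apply it to the
#' image. An empty predicted cell mask — or a nucleus prediction covering the
#' whole predicted cell — leaves no cytoplasm and is raised as a
#' segmentation-failure error so the cell can be flagged and excluded
#' downstream.
#'
#' @param cellBundle,nucleusBundle trained \linkS4class{SegModelBundle}s for
#'   the cell and nucleus targets.
#' @param image a \linkS4class{CellImage}.
#' @return list with \code{mask} (the cytoplasm \linkS4class{BinaryMask}) and
#'   \code{masked} (the blacked-out \linkS4class{CellImage}).
#' @export
segmentCytoplasm <- function(cellBundle, nucleusBundle, image) {
  cellPred <- predictMask(cellBundle, image)
  if (nForeground(cellPred) == 0L)
    vqError("segmentation failure: empty predicted cell mask", "vq_segfail_error")
  nucPred <- predictMask(nucleusBundle, image)
  cyto <- cytoplasmMask(cellPred, nucPred)
  if (nForeground(cyto) == 0L)
    vqError("segmentation failure: empty cytoplasm (nucleus covers predicted cell)",
            "vq_segfail_error")
  list(mask = cyto, masked = applyMask(image, cyto))
}

#' Save or load a model bundle
#'
#' Bundles are serialized as a directory holding the weights in a plain-text
#' representation (one CSV per parameter array) and a JSON sidecar with the
#' configuration and validation metrics.
#'
#' @param bundle a \linkS4class{SegModelBundle} or \linkS4class{ClsModelBundle}.
#' @param dir directory to write/read.
#' @return \code{saveModelBundle} returns \code{dir} invisibly;
#'   \code{loadModelBundle} returns the bundle.
#' @export
saveModelBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wdir <- file.path(dir, "weights")
  dir.create(wdir, showWarnings = FALSE)
  shapes <- lapply(bundle@weights, function(w) if (is.matrix(w)) dim(w) else length(w))
  for (nm in names(bundle@weights)) {
    w <- bundle@weights[[nm]]
    utils::write.table(as.numeric(w), file.path(wdir, paste0(nm, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  kind <- if (is(bundle, "SegModelBundle")) "segmentation" else "classification"
  cfg <- bundle@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s), simplify = FALSE)
  meta <- list(kind = kind, config = cfgList, shapes = shapes,
               metric = if (kind == "segmentation") bundle@validationDice
                        else bundle@validationAccuracy,
               history = bundle@history)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  metaPath <- file.path(dir, "bundle.json")
  if (!file.exists(metaPath)) vqError(sprintf("no bundle at %s", dir), "vq_io_error")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  weights <- list()
  for (nm in names(meta$shapes)) {
    v <- scan(file.path(dir, "weights", paste0(nm, ".txt")), quiet = TRUE)
    shp <- meta$shapes[[nm]]
    weights[[nm]] <- if (length(shp) == 2L) matrix(v, shp[1], shp[2]) else v
  }
  hist <- as.data.frame(meta$history)
  cfg <- meta$config
  if (meta$kind == "segmentation") {
    config <- segTrainConfig(target = cfg$target, splitFraction = cfg$splitFraction,
                             epochs = cfg$epochs, batchSize = cfg$batchSize,
                             learningRate = cfg$learningRate,
                             binarizationThreshold = cfg$binarizationThreshold,
                             depth = cfg$depth, baseFilters = cfg$baseFilters,
                             seed = cfg$seed)
    new("SegModelBundle", weights = weights, config = config,
        validationDice = meta$metric, history = hist)
  } else {
    config <- clsTrainConfig(splitFraction = cfg$splitFraction, epochs = cfg$epochs,
                             batchSize = cfg$batchSize, learningRate = cfg$learningRate,
                             baseFilters = cfg$baseFilters,
                             blocksPerStage = cfg$blocksPerStage, seed = cfg$seed)
    new("ClsModelBundle", weights = weights, config = config,
        validationAccuracy = meta$metric, history = hist)
  }
}
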