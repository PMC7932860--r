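#' @include AllClasses.R AllGenerics.R utils.R nn-core.R resnet.R augment.R seg-model.R
NULL

#' Construct a classifier training configuration
#'
#' @param splitFraction training proportion; default 0.8.
#' @param epochs training epochs; default 12, with the best
#'   validation-accuracy state checkpointed and returned, so additional
#'   epochs cannot degrade the reported model.
#' @param batchSize default 16.
#' @param learningRate Adam step size; default 2e-3.
#' @param baseFilters first-stage channels (doubling per stage); default 8.
#' @param blocksPerStage residual blocks per stage; default 2.
#' @param seed integer.
#' @return a \linkS4class{ClsTrainConfig}.
#' @export
clsTrainConfig <- function(splitFraction = 0.8, epochs = 12L, batchSize = 16L,
                           learningRate = 2e-3, baseFilters = 8L,
                           blocksPerStage = 2L, seed = 1L) {
  tryCatch(
    new("ClsTrainConfig", splitFraction = splitFraction, epochs = as.integer(epochs),
        batchSize = as.integer(batchSize), learningRate = learningRate,
        baseFilters = as.integer(baseFilters), blocksPerStage = as.integer(blocksPerStage),
        seed = as.integer(seed)),
    error = function(e) vqError(conditionMessage(e), "vq_parameter_error"))
}

.labelIndex <- function(image) {
  if (is.na(image@label)) vqError("example lacks a label", "vq_data_error")
  if (image@label == "vacuolated") 1L else 2L
}

.valAccuracy <- function(params, Xva, yva, blocksPerStage, chunk = 16L) {
  n <- dim(Xva)[3]
  correct <- 0L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- resnetForward(params, Xva[, , idx, , drop = FALSE], blocksPerStage, keepCache = FALSE)
    correct <- correct + sum(max.col(fw$prob) == yva[idx])
  }
  correct / n
}

#' Train the vacuolization classifier
#'
#' Fits the residual classifier with its 2-neuron softmax head on
#' cytoplasm-masked, labeled cell images using Adam on the cross-entropy
#' loss, after an internal train/validation split. Training runs a fixed
#' number of epochs and the parameter state with the best validation
#' accuracy is the one returned (additional epochs cannot degrade the
#' reported model).
#'
#' Small networks without normalization layers occasionally sit on a
#' no-learning plateau whose length depends on the weight initialization.
#' Training therefore uses seeded random restarts: an attempt whose
#' validation accuracy is still near chance after an initial grace period is
#' abandoned and training restarts from a fresh derived initialization (up
#' to \code{maxRestarts} attempts); the best checkpoint across attempts is
#' returned. The whole protocol is deterministic given the config seed.
#'
#' @param examples list of labeled \linkS4class{CellImage} (cytoplasm-masked);
#'   both classes must be present in the training portion.
#' @param config a \linkS4class{ClsTrainConfig}.
#' @param augment optional \linkS4class{AugmentationConfig}; when given, the
#'   training portion (only) is expanded after the split (labels are
#'   invariant under the geometric transforms).
#' @param maxRestarts maximum training attempts from fresh initializations;
#'   default 3.
#' @param quiet suppress per-epoch progress; default TRUE.
#' @return a \linkS4class{ClsModelBundle}; the history carries an
#'   \code{attempt} column.
#' @export
trainClassifier <- function(examples, config = clsTrainConfig(), augment = NULL,
                            maxRestarts = 3L, quiet = TRUE) {
  if (!is(config, "ClsTrainConfig")) vqError("config must be a ClsTrainConfig", "vq_parameter_error")
  y <- vapply(examples, .labelIndex, integer(1))
  sp <- splitDataset(seq_along(examples), config@splitFraction, config@seed)
  trIdx <- unlist(sp$train); vaIdx <- unlist(sp$validation)
  if (length(unique(y[trIdx])) < 2L)
    vqError("training portion must contain both classes", "vq_data_error")
  trainEx <- examples[trIdx]
  if (!is.null(augment)) trainEx <- augmentDataset(trainEx, augment)
  ## intensities are centered at zero for the classifier: masked crops are
  ## dominated by black background, and uncentered inputs slow down the
  ## early symmetry breaking of the unnormalized network
  Xtr <- nnStackImages(trainEx) - 0.5
  ytr <- vapply(trainEx, .labelIndex, integer(1))
  Xva <- nnStackImages(examples[vaIdx]) - 0.5
  yva <- y[vaIdx]
  if (dim(Xtr)[1] %% 4L != 0L)
    vqError("image side must be divisible by 4 (two pooling stages)", "vq_shape_error")
  nTrain <- dim(Xtr)[3]

  ## an attempt is abandoned when validation accuracy is still below this
  ## bar after graceEpochs (plateau diagnostic); restarting is cheaper than
  ## waiting out a long plateau
  graceEpochs <- min(6L, config@epochs)
  plateauBar <- 0.75
  goodEnough <- 0.9

  best <- list(acc = -1, params = NULL, epoch = 0L)
  history <- data.frame(attempt = integer(), epoch = integer(),
                        loss = numeric(), val_accuracy = numeric())
  for (attempt in seq_len(max(1L, maxRestarts))) {
    initSeed <- if (attempt == 1L) config@seed else deriveSeed(config@seed, 7000L + attempt)
    params <- withSeed(initSeed, resnetInit(config@baseFilters, config@blocksPerStage))
    state <- adamInit(params)
    attemptBest <- -1
    withSeed(deriveSeed(initSeed, 29L), {
      for (ep in seq_len(config@epochs)) {
        ord <- sample.int(nTrain)
        epLoss <- 0; nb <- 0L
        for (start in seq(1L, nTrain, by = config@batchSize)) {
          idx <- ord[start:min(start + config@batchSize - 1L, nTrain)]
          fw <- resnetForward(params, Xtr[, , idx, , drop = FALSE], config@blocksPerStage)
          ls <- softmaxXent(fw$prob, ytr[idx])
          if (!is.finite(ls$loss)) vqError("non-finite training loss", "vq_model_error")
          gr <- resnetBackward(params, ls$dLogits, fw, config@blocksPerStage)
          up <- adamStep(params, gr, state, config@learningRate)
          params <- up$params; state <- up$state
          epLoss <- epLoss + ls$loss; nb <- nb + 1L
        }
        acc <- .valAccuracy(params, Xva, yva, config@blocksPerStage)
        history <- rbind(history, data.frame(attempt = attempt, epoch = ep,
                                             loss = epLoss / nb, val_accuracy = acc))
        attemptBest <- max(attemptBest, acc)
        if (acc > best$acc) best <- list(acc = acc, params = params, epoch = ep)
        if (!quiet) message(sprintf("[cls attempt %d] epoch %d  loss %.4f  val acc %.4f",
                                    attempt, ep, epLoss / nb, acc))
        if (ep == graceEpochs && attemptBest < plateauBar) break
      }
    })
    if (best$acc >= goodEnough) break
  }
  new("ClsModelBundle", weights = best$params, config = config,
      validationAccuracy = best$acc, history = history)
}

#' Classify one cytoplasm-masked cell image
#'
#' @param bundle a trained \linkS4class{ClsModelBundle}.
#' @param image a \linkS4class{CellImage} (cytoplasm-masked).
#' @return a \linkS4class{ProbabilityVector} (softmax-normalized).
#' @export
classify <- function(bundle, image) {
  if (!is(bundle, "ClsModelBundle")) vqError("bundle must be a ClsModelBundle", "vq_model_error")
  d <- dim(image@pixels)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    vqError("image dimensions incompatible with the classifier's pooling", "vq_shape_error")
  X <- array(image@pixels - 0.5, c(d[1], d[2], 1L, 3L))  # same centering as training
  fw <- resnetForward(bundle@weights, X, bundle@config@blocksPerStage, keepCache = FALSE)
  probabilityVector(fw$prob[1, 1])
}

#' The vacuolization decision rule
#'
#' A cell is called vacuolated when the probability of the vacuolated class
#' is greater than or equal to the threshold (inclusive: a probability of
#' exactly 65% with the default tau = 0.65 is a positive call).
#'
#' @param p a \linkS4class{ProbabilityVector}.
#' @param threshold a \linkS4class{DecisionThreshold}.
#' @return logical.
#' @export
setMethod("isVacuolated", signature("ProbabilityVector", "DecisionThreshold"),
          function(p, threshold) p@pVacuolated >= threshold@tau)

#' Grad-CAM attribution map for the classifier
#'
#' Gradient-weighted class activation mapping over the last convolutional
#' stage: gradients of the target-class score (pre-softmax logit) with
#' respect to the stage's feature maps are spatially pooled into channel
#' importance weights, the weighted feature maps are summed and rectified,
#' then upsampled to the input resolution and normalized to [0, 1]. On a
#' well-trained model the hot regions coincide with the vacuoles that drive
#' the vacuolated-class score.
#'
#' @param bundle a trained \linkS4class{ClsModelBundle}.
#' @param image a \linkS4class{CellImage}.
#' @param targetClass "vacuolated" (default) or "healthy".
#' @return a \linkS4class{GradCamMap}; identically zero when the rectified
#'   raw map is zero everywhere.
#' @export
gradCam <- function(bundle, image, targetClass = c("vacuolated", "healthy")) {
  targetClass <- match.arg(targetClass)
  if (!is(bundle, "ClsModelBundle") || length(bundle@weights) == 0L)
    vqError("bundle must be a trained ClsModelBundle", "vq_model_error")
  d <- dim(image@pixels)
  X <- array(image@pixels - 0.5, c(d[1], d[2], 1L, 3L))  # same centering as training
  fw <- resnetForward(bundle@weights, X, bundle@config@blocksPerStage, keepCache = FALSE)
  col <- if (targetClass == "vacuolated") 1L else 2L
  dLogits <- matrix(0, 1, 2)
  dLogits[1, col] <- 1
  dA <- resnetBackward(bundle@weights, dLogits, fw, bundle@config@blocksPerStage,
                       toStage3Only = TRUE)
  alpha <- apply(dA[, , 1, , drop = FALSE], 4, mean)      # channel weights
  A <- fw$stage3[, , 1, ]
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * A[, , k]
  cam[cam < 0] <- 0
  if (max(cam) > 0) {
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(cam), w = d[1], h = d[2]))
    up[up < 0] <- 0
    up <- up / max(up)
  } else {
    up <- matrix(0, d[1], d[2])
  }
  new("GradCamMap", heatmap = up, targetClass = targetClass)
}

#' Write a Grad-CAM map as a PNG overlay plus a raw CSV
#'
#' The overlay blends the (red-tinted) heatmap onto the input image; the raw
#' normalized map is written alongside as CSV for downstream analysis.
#'
#' @param map a \linkS4class{GradCamMap}.
#' @param image the \linkS4class{CellImage} it was computed on.
#' @param path output PNG path (the CSV takes the same stem).
#' @return the PNG path, invisibly.
#' @export
writeGradCamOverlay <- function(map, image, path) {
  h <- map@heatmap
  px <- image@pixels
  overlay <- px
  overlay[, , 1] <- clamp01(px[, , 1] * (1 - 0.6 * h) + 0.6 * h)
  overlay[, , 2] <- px[, , 2] * (1 - 0.6 * h)
  overlay[, , 3] <- px[, , 3] * (1 - 0.6 * h)
  png::writePNG(overlay, path)
  utils::write.table(h, sub("\\.png$", ".csv", path), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
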