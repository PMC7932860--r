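#' @include AllClasses.R synthetic.R augment.R seg-model.R cls-model.R pipeline.R method-comparison.R
NULL

#' Read and validate a dataset manifest
#'
#' @param path manifest CSV (columns smear_id, cell_id, file, label, ...).
#' @param imageDir when given, every referenced image file is checked and
#'   missing files are reported with their row numbers.
#' @return the manifest data.frame.
#' @export
readManifest <- function(path, imageDir = NULL) {
  if (!file.exists(path)) vqError(sprintf("manifest not found: %s", path), "vq_io_error")
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(mf) == 0L) vqError("manifest is empty", "vq_parameter_error")
  need <- c("smear_id", "cell_id", "file", "label")
  missingCols <- setdiff(need, names(mf))
  if (length(missingCols))
    vqError(sprintf("manifest lacks columns: %s", paste(missingCols, collapse = ", ")),
            "vq_io_error")
  bad <- which(!mf$label %in% c("vacuolated", "healthy"))
  if (length(bad))
    vqError(sprintf("manifest rows with invalid labels: %s", paste(bad, collapse = ", ")),
            "vq_io_error")
  if (!is.null(imageDir)) {
    missing <- which(!file.exists(file.path(imageDir, mf$file)))
    if (length(missing))
      vqError(sprintf("manifest rows reference missing images (rows %s)",
                      paste(missing, collapse = ", ")), "vq_io_error")
  }
  mf
}

## ---- JSON report round-trip ----

.vacResultToList <- function(r) {
  list(type = "VacuolizationResult", smear_id = r@smearId,
       n_cells_total = r@nCellsTotal, n_cells_excluded = r@nCellsExcluded,
       n_vacuolated = r@nVacuolated, percent_vacuolated = r@percentVacuolated,
       per_cell = r@perCell)
}

.baToList <- function(b) if (is.null(b)) NULL else
  list(mean_difference = b@meanDifference, sd_difference = b@sdDifference,
       loa_low = b@loa[1], loa_high = b@loa[2], n = b@n)

.cmpToList <- function(r) {
  pb <- r@passingBablok
  list(type = "MethodComparisonResult",
       passing_bablok = if (is.null(pb)) NULL else
         list(slope = pb@slope, intercept = pb@intercept,
              slope_ci = pb@slopeCI, intercept_ci = pb@interceptCI,
              n_pairwise_slopes = pb@nPairwiseSlopes,
              bootstrap_samples = pb@bootstrapSamples, seed = pb@seed),
       bland_altman_auto_vs_consensus = .baToList(r@blandAltmanAuto),
       bland_altman_manual1_vs_manual2 = .baToList(r@blandAltmanManual),
       pearson_r = r@pearson,
       levene = if (is.null(r@levene)) NULL else
         list(W = r@levene@W, df_between = r@levene@dfBetween,
              df_within = r@levene@dfWithin, p_value = r@levene@pValue,
              group_labels = r@levene@groupLabels),
       flags = r@flags)
}

#' Write or read a result report as JSON
#'
#' \linkS4class{VacuolizationResult} and \linkS4class{MethodComparisonResult}
#' objects round-trip losslessly (full numeric precision).
#'
#' @param result a result object.
#' @param path JSON file path.
#' @return \code{writeReport} returns the path invisibly; \code{readReport}
#'   the reconstructed object.
#' @export
writeReport <- function(result, path) {
  lst <- if (is(result, "VacuolizationResult")) .vacResultToList(result)
         else if (is(result, "MethodComparisonResult")) .cmpToList(result)
         else vqError("unsupported report type", "vq_parameter_error")
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) vqError(sprintf("report not found: %s", path), "vq_io_error")
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(lst$type, "VacuolizationResult")) {
    new("VacuolizationResult", smearId = lst$smear_id,
        nCellsTotal = as.integer(lst$n_cells_total),
        nCellsExcluded = as.integer(lst$n_cells_excluded),
        nVacuolated = as.integer(lst$n_vacuolated),
        percentVacuolated = lst$percent_vacuolated,
        perCell = as.data.frame(lst$per_cell))
  } else if (identical(lst$type, "MethodComparisonResult")) {
    pb <- if (is.null(lst$passing_bablok)) NULL else
      new("PassingBablokFit", slope = lst$passing_bablok$slope,
          intercept = lst$passing_bablok$intercept,
          slopeCI = lst$passing_bablok$slope_ci,
          interceptCI = lst$passing_bablok$intercept_ci,
          nPairwiseSlopes = as.integer(lst$passing_bablok$n_pairwise_slopes),
          bootstrapSamples = as.integer(lst$passing_bablok$bootstrap_samples),
          seed = as.integer(lst$passing_bablok$seed))
    baFrom <- function(b) if (is.null(b)) NULL else
      new("BlandAltmanResult", meanDifference = b$mean_difference,
          sdDifference = b$sd_difference, loa = c(b$loa_low, b$loa_high),
          n = as.integer(b$n))
    lv <- if (is.null(lst$levene)) NULL else
      new("LeveneResult", W = lst$levene$W,
          dfBetween = as.integer(lst$levene$df_between),
          dfWithin = as.integer(lst$levene$df_within),
          pValue = lst$levene$p_value, groupLabels = lst$levene$group_labels)
    new("MethodComparisonResult", passingBablok = pb,
        blandAltmanAuto = baFrom(lst$bland_altman_auto_vs_consensus),
        blandAltmanManual = baFrom(lst$bland_altman_manual1_vs_manual2),
        pearson = if (is.null(lst$pearson_r)) NA_real_ else lst$pearson_r,
        levene = lv,
        flags = if (length(lst$flags)) as.character(lst$flags) else character())
  } else vqError("unrecognized report type", "vq_io_error")
}

## ---- workflow configuration ----

#' Construct the end-to-end workflow configuration
#'
#' One global seed deterministically derives every stage seed; any stage
#' config can still be overridden wholesale.
#'
#' @param outDir artifact directory.
#' @param synth \linkS4class{SyntheticParams}; default 64 px crops.
#' @param nSmears,cellsPerSmear,fractions quantification dataset shape;
#'   defaults: 8 smears of 30 cells spanning vacuolated fractions 0-0.7.
#' @param augment \linkS4class{AugmentationConfig} (applied to training
#'   portions after the split); NULL disables augmentation.
#' @param segCell,segNucleus,cls stage training configs.
#' @param threshold \linkS4class{DecisionThreshold}; default tau = 0.65.
#' @param nSegCells,nClsCells training pool sizes; defaults 200 and 400.
#' @param bootstrapSamples Passing-Bablok bootstrap resamples; default 999.
#' @param raterNoiseSd SD (percentage points) of the two simulated manual
#'   raters used in the comparison stage; default 2.
#' @param seed global seed.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir = "vacuoquant_run",
                           synth = syntheticParams(imageSize = 64L),
                           nSmears = 8L, cellsPerSmear = 30L,
                           fractions = seq(0, 0.7, length.out = nSmears),
                           augment = NULL,
                           segCell = segTrainConfig("cell", seed = deriveSeed(seed, 1L)),
                           segNucleus = segTrainConfig("nucleus", seed = deriveSeed(seed, 2L)),
                           cls = clsTrainConfig(seed = deriveSeed(seed, 3L)),
                           threshold = decisionThreshold(0.65),
                           nSegCells = 200L, nClsCells = 400L,
                           bootstrapSamples = 999L, raterNoiseSd = 2,
                           seed = 1L) {
  tryCatch({
    obj <- new("PipelineConfig", outDir = outDir, synth = synth,
               nSmears = as.integer(nSmears), cellsPerSmear = as.integer(cellsPerSmear),
               fractions = as.numeric(fractions),
               augment = if (is.null(augment)) augmentationConfig(factor = 1L) else augment,
               segCell = segCell, segNucleus = segNucleus, cls = cls,
               threshold = threshold, nSegCells = as.integer(nSegCells),
               nClsCells = as.integer(nClsCells),
               bootstrapSamples = as.integer(bootstrapSamples),
               raterNoiseSd = raterNoiseSd, seed = as.integer(seed))
    attr(obj, "augmentEnabled") <- !is.null(augment)
    obj
  }, error = function(e) {
    if (inherits(e, "vq_error")) stop(e)
    vqError(conditionMessage(e), "vq_parameter_error")
  })
}

#' Write / read the workflow configuration as YAML
#'
#' The YAML representation round-trips losslessly into an equal
#' \linkS4class{PipelineConfig}.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path YAML file path.
#' @return \code{writePipelineConfig} returns the path invisibly;
#'   \code{readPipelineConfig} the reconstructed config.
#' @export
writePipelineConfig <- function(config, path) {
  slots2list <- function(obj) sapply(slotNames(obj), function(s) slot(obj, s), simplify = FALSE)
  lst <- list(
    out_dir = config@outDir,
    seed = config@seed,
    synth = slots2list(config@synth),
    dataset = list(n_smears = config@nSmears, cells_per_smear = config@cellsPerSmear,
                   fractions = config@fractions),
    augment = c(slots2list(config@augment),
                list(enabled = isTRUE(attr(config, "augmentEnabled")))),
    seg_cell = slots2list(config@segCell),
    seg_nucleus = slots2list(config@segNucleus),
    cls = slots2list(config@cls),
    threshold = list(tau = config@threshold@tau),
    training = list(n_seg_cells = config@nSegCells, n_cls_cells = config@nClsCells),
    comparison = list(bootstrap_samples = config@bootstrapSamples,
                      rater_noise_sd = config@raterNoiseSd))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) vqError(sprintf("config not found: %s", path), "vq_io_error")
  l <- yaml::read_yaml(path)
  sy <- l$synth
  synth <- syntheticParams(imageSize = sy$imageSize, cellRadiusRange = unlist(sy$cellRadiusRange),
                           nucleusAreaFractionRange = unlist(sy$nucleusAreaFractionRange),
                           vacuoleCountRange = unlist(sy$vacuoleCountRange),
                           vacuoleRadiusRange = unlist(sy$vacuoleRadiusRange),
                           boundaryIrregularity = sy$boundaryIrregularity,
                           stainPalette = lapply(sy$stainPalette, unlist),
                           noiseSd = sy$noiseSd, clutterCount = sy$clutterCount,
                           seed = sy$seed)
  au <- l$augment
  augment <- if (isTRUE(au$enabled))
    augmentationConfig(factor = au$factor, rotationMaxDeg = au$rotationMaxDeg,
                       shiftMaxFraction = au$shiftMaxFraction, shearMaxDeg = au$shearMaxDeg,
                       zoomRange = unlist(au$zoomRange), allowFlips = unlist(au$allowFlips),
                       seed = au$seed) else NULL
  segFrom <- function(s) segTrainConfig(target = s$target, splitFraction = s$splitFraction,
    epochs = s$epochs, batchSize = s$batchSize, learningRate = s$learningRate,
    binarizationThreshold = s$binarizationThreshold, depth = s$depth,
    baseFilters = s$baseFilters, seed = s$seed)
  cl <- l$cls
  pipelineConfig(outDir = l$out_dir, synth = synth, nSmears = l$dataset$n_smears,
                 cellsPerSmear = l$dataset$cells_per_smear,
                 fractions = unlist(l$dataset$fractions), augment = augment,
                 segCell = segFrom(l$seg_cell), segNucleus = segFrom(l$seg_nucleus),
                 cls = clsTrainConfig(splitFraction = cl$splitFraction, epochs = cl$epochs,
                                      batchSize = cl$batchSize, learningRate = cl$learningRate,
                                      baseFilters = cl$baseFilters,
                                      blocksPerStage = cl$blocksPerStage, seed = cl$seed),
                 threshold = decisionThreshold(l$threshold$tau),
                 nSegCells = l$training$n_seg_cells, nClsCells = l$training$n_cls_cells,
                 bootstrapSamples = l$comparison$bootstrap_samples,
                 raterNoiseSd = l$comparison$rater_noise_sd, seed = l$seed)
}

## Generate a labeled training pool of single cells (50/50 classes), with
## ground-truth masks; shared by the workflow and the acceptance script.

#' Generate a balanced pool of labeled synthetic cells
#'
#' @param n number of cells (alternating vacuolated/healthy).
#' @param params \linkS4class{SyntheticParams}.
#' @param seed integer.
#' @return list of \linkS4class{CellImage}.
#' @export
generateCellPool <- function(n, params = syntheticParams(), seed = params@seed) {
  lapply(seq_len(n), function(i)
    generateCell(params, vacuolated = i %% 2L == 1L, seed = deriveSeed(seed, 7000L + i)))
}

#' Mask a cell with its ground-truth cytoplasm
#'
#' Convenience used when training the classifier on oracle segmentation:
#' cytoplasm = cell mask minus nucleus mask, applied to the pixels.
#'
#' @param cell a \linkS4class{CellImage} with cell and nucleus masks.
#' @return the masked \linkS4class{CellImage}.
#' @export
maskWithTruth <- function(cell) {
  applyMask(cell, cytoplasmMask(cell@cellMask, cell@nucleusMask))
}

#' Run the full workflow end to end
#'
#' Executes, in order: synthetic dataset generation, segmentation training
#' (cell and nucleus, with optional post-split augmentation), classifier
#' training on ground-truth-masked cells, per-smear quantification with the
#' trained pipeline, and the method comparison against two simulated manual
#' raters (ground-truth percentage plus independent Gaussian noise). Every
#' artifact directory receives a JSON provenance sidecar (config file hash,
#' seed, package and R versions). A failing stage aborts with a stage-tagged
#' error; artifacts of completed stages are retained.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param quiet suppress progress messages.
#' @return list with the trained bundles, the per-smear table, and the
#'   \linkS4class{MethodComparisonResult}, invisibly.
#' @export
runFullWorkflow <- function(config, quiet = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      vqError(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), "vq_stage_error"))
  }
  augment <- if (isTRUE(attr(config, "augmentEnabled"))) config@augment else NULL
  out <- config@outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(out, "config.yaml")
  writePipelineConfig(config, cfgPath)
  provenance <- list(config_hash = unname(tools::md5sum(cfgPath)), seed = config@seed,
                     package_version = as.character(utils::packageVersion("vacuoquant")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"), auto_unbox = TRUE)

  dataDir <- file.path(out, "data")
  manifest <- stage("synth", generateDataset(config@nSmears, config@fractions,
                                             config@synth, dataDir,
                                             cellsPerSmear = config@cellsPerSmear,
                                             seed = deriveSeed(config@seed, 11L)))
  if (!quiet) message("synth: ", nrow(manifest), " cells across ", config@nSmears, " smears")

  segPool <- stage("synth", generateCellPool(config@nSegCells, config@synth,
                                             seed = deriveSeed(config@seed, 12L)))
  cellBundle <- stage("train-seg-cell",
                      trainSegmenter(segPool, config@segCell, augment = augment, quiet = quiet))
  nucleusBundle <- stage("train-seg-nucleus",
                         trainSegmenter(segPool, config@segNucleus, augment = augment, quiet = quiet))
  stage("train-seg-cell", saveModelBundle(cellBundle, file.path(out, "models", "cell")))
  stage("train-seg-nucleus", saveModelBundle(nucleusBundle, file.path(out, "models", "nucleus")))

  clsPool <- stage("synth", generateCellPool(config@nClsCells, config@synth,
                                             seed = deriveSeed(config@seed, 13L)))
  clsBundle <- stage("train-cls",
                     trainClassifier(lapply(clsPool, maskWithTruth), config@cls,
                                     augment = augment, quiet = quiet))
  stage("train-cls", saveModelBundle(clsBundle, file.path(out, "models", "classifier")))

  quant <- stage("quantify", quantifyDataset(manifest, dataDir, cellBundle,
                                             nucleusBundle, clsBundle, config@threshold))
  utils::write.csv(quant$smears, file.path(out, "smears.csv"), row.names = FALSE)
  utils::write.csv(quant$cells, file.path(out, "cells.csv"), row.names = FALSE)

  cmp <- stage("compare", {
    truth <- quant$smears$truth_percent
    noise <- withSeed(deriveSeed(config@seed, 14L),
                      matrix(stats::rnorm(2 * length(truth), sd = config@raterNoiseSd),
                             ncol = 2))
    manual1 <- pmin(100, pmax(0, truth + noise[, 1]))
    manual2 <- pmin(100, pmax(0, truth + noise[, 2]))
    compareMethods(quant$smears$percent, manual1, manual2,
                   bootstrapSamples = config@bootstrapSamples,
                   seed = deriveSeed(config@seed, 15L))
  })
  writeReport(cmp, file.path(out, "comparison.json"))
  invisible(list(cellBundle = cellBundle, nucleusBundle = nucleusBundle,
                 clsBundle = clsBundle, smears = quant$smears, comparison = cmp))
}
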