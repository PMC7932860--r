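#' @include AllClasses.R seg-model.R cls-model.R
NULL

#' Quantify vacuolization in one smear
#'
#' Runs every cell through the full deployed pipeline — cell and nucleus
#' segmentation, cytoplasm masking, classification, threshold decision — and
#' aggregates to the smear's percent vacuolated:
#' 100 * n_vacuolated / (n_total - n_excluded). Cells whose segmentation
#' fails (no usable cytoplasm) are excluded from the denominator and
#' reported, never silently dropped.
#'
#' @param cellImages nonempty list of \linkS4class{CellImage}.
#' @param cellBundle,nucleusBundle trained \linkS4class{SegModelBundle}s.
#' @param clsBundle trained \linkS4class{ClsModelBundle}.
#' @param threshold a \linkS4class{DecisionThreshold}; default 0.65.
#' @param smearId identifier for the result.
#' @param cellIds optional per-cell identifiers.
#' @return a \linkS4class{VacuolizationResult} with per-cell probabilities
#'   retained, so alternative thresholds can be re-applied without
#'   re-running inference.
#' @export
quantifySmear <- function(cellImages, cellBundle, nucleusBundle, clsBundle,
                          threshold = decisionThreshold(), smearId = "smear",
                          cellIds = NULL) {
  if (length(cellImages) == 0L)
    vqError("need at least one cell image", "vq_parameter_error")
  n <- length(cellImages)
  if (is.null(cellIds)) cellIds <- sprintf("%s_c%03d", smearId, seq_len(n))
  p <- rep(NA_real_, n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    seg <- tryCatch(segmentCytoplasm(cellBundle, nucleusBundle, cellImages[[i]]),
                    vq_segfail_error = function(e) NULL)
    if (is.null(seg)) {
      excluded[i] <- TRUE
      next
    }
    p[i] <- classify(clsBundle, seg$masked)@pVacuolated
  }
  if (all(excluded))
    vqError("quantification failure: every cell was excluded by segmentation",
            "vq_quantification_error")
  decision <- !excluded & !is.na(p) & p >= threshold@tau
  nKept <- n - sum(excluded)
  perCell <- data.frame(cell_id = cellIds, p_vacuolated = p,
                        decision = decision, excluded = excluded,
                        stringsAsFactors = FALSE)
  new("VacuolizationResult", smearId = smearId, nCellsTotal = as.integer(n),
      nCellsExcluded = as.integer(sum(excluded)),
      nVacuolated = as.integer(sum(decision)),
      percentVacuolated = 100 * sum(decision) / nKept, perCell = perCell)
}

#' Quantify every smear of a dataset manifest
#'
#' Groups the manifest by smear, loads each cell crop, runs
#' \code{\link{quantifySmear}}, and returns one result per smear together
#' with tabular reports ready for method comparison.
#'
#' @param manifest data.frame as written by \code{\link{generateDataset}}
#'   (columns smear_id, cell_id, file, label, ...), or a path to such a CSV.
#' @param imageDir directory the manifest's file column is relative to.
#' @param cellBundle,nucleusBundle,clsBundle trained model bundles.
#' @param threshold a \linkS4class{DecisionThreshold}.
#' @return list with \code{results} (list of \linkS4class{VacuolizationResult}),
#'   \code{smears} (per-smear data.frame: smear_id, n_total, n_excluded,
#'   n_vacuolated, percent, truth_percent when labels are present) and
#'   \code{cells} (per-cell data.frame).
#' @export
quantifyDataset <- function(manifest, imageDir, cellBundle, nucleusBundle,
                            clsBundle, threshold = decisionThreshold()) {
  if (is.character(manifest)) manifest <- readManifest(manifest, imageDir)
  smearIds <- unique(manifest$smear_id)
  results <- vector("list", length(smearIds))
  names(results) <- smearIds
  for (sid in smearIds) {
    rows <- manifest[manifest$smear_id == sid, , drop = FALSE]
    paths <- file.path(imageDir, rows$file)
    missing <- !file.exists(paths)
    if (any(missing))
      vqError(sprintf("manifest rows reference missing images: %s",
                      paste(rows$cell_id[missing], collapse = ", ")), "vq_io_error")
    cells <- lapply(paths, readImagePNG)
    results[[sid]] <- quantifySmear(cells, cellBundle, nucleusBundle, clsBundle,
                                    threshold, smearId = sid, cellIds = rows$cell_id)
  }
  smears <- do.call(rbind, lapply(results, function(r)
    data.frame(smear_id = r@smearId, n_total = r@nCellsTotal,
               n_excluded = r@nCellsExcluded, n_vacuolated = r@nVacuolated,
               percent = r@percentVacuolated, stringsAsFactors = FALSE)))
  rownames(smears) <- NULL
  if ("label" %in% names(manifest)) {
    truth <- tapply(manifest$label == "vacuolated", manifest$smear_id, mean) * 100
    smears$truth_percent <- as.numeric(truth[smears$smear_id])
  }
  cells <- do.call(rbind, lapply(results, function(r) {
    pc <- r@perCell
    pc$smear_id <- r@smearId
    pc
  }))
  rownames(cells) <- NULL
  list(results = results, smears = smears, cells = cells)
}
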