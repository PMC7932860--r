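#' @include AllClasses.R AllGenerics.R utils.R mask-ops.R
NULL

#' Construct synthetic-generator parameters
#'
#' Defaults emulate a May-Grünwald-Giemsa stained lymphocyte crop: pale
#' background, pale-blue cytoplasm rim, a large dark purple nucleus occupying
#' 55-70% of the cell area, and near-white round vacuole clearings. The
#' geometric defaults scale with \code{imageSize} so the same morphology is
#' produced at any crop size.
#'
#' @param imageSize pixels per side (square crop); default 128.
#' @param cellRadiusRange min/max cell radius (pixels); default 0.22-0.32 of the side.
#' @param nucleusAreaFractionRange default c(0.55, 0.70).
#' @param vacuoleCountRange default c(1, 5) vacuoles per vacuolated cell.
#' @param vacuoleRadiusRange default 0.025-0.045 of the side (>= 1.2 px).
#' @param boundaryIrregularity amplitude of the periodic radial perturbation
#'   of the cell/nucleus boundaries; default 0.08.
#' @param stainPalette named list of mean RGB triplets.
#' @param noiseSd additive Gaussian pixel noise SD; default 0.02.
#' @param clutterCount distractor discs on the background; default 0.
#' @param seed base seed; default 1.
#' @return a \linkS4class{SyntheticParams}.
#' @examples
#' p <- syntheticParams(imageSize = 64)
#' cell <- generateCell(p, vacuolated = TRUE, seed = 3)
#' @export
syntheticParams <- function(imageSize = 128L,
                            cellRadiusRange = imageSize * c(0.22, 0.32),
                            nucleusAreaFractionRange = c(0.55, 0.70),
                            vacuoleCountRange = c(1L, 5L),
                            vacuoleRadiusRange = pmax(1.2, imageSize * c(0.025, 0.045)),
                            boundaryIrregularity = 0.08,
                            stainPalette = list(
                              background = c(0.93, 0.92, 0.95),
                              cytoplasm  = c(0.62, 0.71, 0.85),
                              nucleus    = c(0.33, 0.21, 0.46),
                              vacuole    = c(0.90, 0.92, 0.95)),
                            noiseSd = 0.02,
                            clutterCount = 0L,
                            seed = 1L) {
  obj <- tryCatch(
    new("SyntheticParams", imageSize = as.integer(imageSize),
        cellRadiusRange = as.numeric(cellRadiusRange),
        nucleusAreaFractionRange = as.numeric(nucleusAreaFractionRange),
        vacuoleCountRange = as.integer(vacuoleCountRange),
        vacuoleRadiusRange = as.numeric(vacuoleRadiusRange),
        boundaryIrregularity = as.numeric(boundaryIrregularity),
        stainPalette = stainPalette, noiseSd = as.numeric(noiseSd),
        clutterCount = as.integer(clutterCount), seed = as.integer(seed)),
    error = function(e) vqError(conditionMessage(e), "vq_parameter_error"))
  obj
}

## Radially perturbed disc: smooth periodic perturbation of a circle with
## two random harmonics, total amplitude bounded by `irregularity`.
## Returns a logical matrix over an imageSize x imageSize grid.
.irregularDisc <- function(size, center, radius, irregularity) {
  amp <- runif(2)
  amp <- amp / sum(amp) * irregularity
  phase <- runif(2, 0, 2 * pi)
  y <- matrix(seq_len(size), size, size) - center[1]
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2]
  theta <- atan2(x, y)
  r <- radius * (1 + amp[1] * sin(2 * theta + phase[1]) + amp[2] * sin(3 * theta + phase[2]))
  sqrt(y^2 + x^2) <= r
}

.discAt <- function(size, center, radius) {
  y <- matrix(seq_len(size), size, size) - center[1]
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - center[2]
  y^2 + x^2 <= radius^2
}

#' Generate one synthetic stained-lymphocyte crop
#'
#' Draws cell and nucleus as radially perturbed discs (the nucleus confined
#' inside the cell with a guaranteed cytoplasm rim), places vacuoles as discs
#' fully inside the cytoplasm by rejection sampling (radius shrinks when a
#' vacuole cannot be placed, down to a single-pixel clearing, so a vacuolated
#' cell always carries at least one vacuole), renders compartment mean colors
#' plus Gaussian pixel noise, and returns the crop with pixel-perfect
#' ground-truth cell/nucleus/vacuole masks and its label.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @param vacuolated logical; draw vacuoles and label accordingly.
#' @param seed integer; the same params + seed reproduce the image bit for bit.
#' @return a \linkS4class{CellImage} with all three masks populated.
#' @export
setMethod("generateCell", signature("SyntheticParams"), function(params, vacuolated, seed) {
  msg <- validObject(params, test = TRUE)
  if (!isTRUE(msg)) vqError(msg, "vq_parameter_error")
  s <- params@imageSize
  withSeed(seed, {
    centerJitter <- runif(2, -0.03, 0.03) * s
    center <- s / 2 + 0.5 + centerJitter
    cellR <- runif(1, params@cellRadiusRange[1], params@cellRadiusRange[2])
    cellG <- .irregularDisc(s, center, cellR, params@boundaryIrregularity)

    ## nucleus: same family of shapes, offset within the cell, clipped to an
    ## inner copy of the cell so a cytoplasm rim always remains
    frac <- runif(1, params@nucleusAreaFractionRange[1], params@nucleusAreaFractionRange[2])
    nucR <- cellR * sqrt(frac)
    offDir <- runif(1, 0, 2 * pi)
    offMag <- runif(1, 0, 0.25) * max(cellR - nucR, 0)
    nucCenter <- center + offMag * c(cos(offDir), sin(offDir))
    nucG <- .irregularDisc(s, nucCenter, nucR, params@boundaryIrregularity)
    inner <- .irregularDisc(s, center, cellR * 0.90, 0)  # rim guarantee
    nucG <- nucG & inner & cellG

    cytoG <- cellG & !nucG
    vacG <- matrix(FALSE, s, s)
    nVac <- 0L
    if (isTRUE(vacuolated)) {
      nVac <- sample(seq(params@vacuoleCountRange[1], params@vacuoleCountRange[2]), 1L)
      for (v in seq_len(nVac)) {
        vr <- runif(1, params@vacuoleRadiusRange[1], params@vacuoleRadiusRange[2])
        placed <- FALSE
        while (!placed) {
          for (attempt in 1:60) {
            cy <- runif(1, center[1] - cellR, center[1] + cellR)
            cx <- runif(1, center[2] - cellR, center[2] + cellR)
            disc <- .discAt(s, c(cy, cx), vr)
            if (any(disc) && !any(disc & !cytoG) && !any(disc & vacG)) {
              vacG <- vacG | disc
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            if (vr > 1) vr <- max(1, vr * 0.7)
            else {  # final fallback: a one-pixel clearing at a free cytoplasm pixel
              free <- which(cytoG & !vacG)
              if (length(free) == 0L) free <- which(cytoG)
              vacG[free[sample.int(length(free), 1L)]] <- TRUE
              placed <- TRUE
            }
          }
        }
      }
    }

    pal <- params@stainPalette
    px <- array(0, dim = c(s, s, 3L))
    for (ch in 1:3) {
      plane <- matrix(pal$background[ch], s, s)
      plane[cytoG] <- pal$cytoplasm[ch]
      plane[nucG] <- pal$nucleus[ch]
      plane[vacG] <- pal$vacuole[ch]
      px[, , ch] <- plane
    }
    if (params@clutterCount > 0L) {
      ## distractor discs in vacuole colors, restricted to the background
      for (k in seq_len(params@clutterCount)) {
        cR <- runif(1, params@vacuoleRadiusRange[1], params@vacuoleRadiusRange[2]) * 1.5
        cc <- runif(2, 1, s)
        disc <- .discAt(s, cc, cR) & !cellG
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[disc] <- pal$vacuole[ch] * 0.92
          px[, , ch] <- plane
        }
      }
    }
    if (params@noiseSd > 0)
      px <- px + rnorm(length(px), sd = params@noiseSd)
    px <- clamp01(px)

    cellImage(px, cellMask = binaryMask(cellG), nucleusMask = binaryMask(nucG),
              vacuoleMask = binaryMask(vacG),
              label = if (isTRUE(vacuolated)) "vacuolated" else "healthy")
  })
})

#' Generate a synthetic smear of known vacuolization fraction
#'
#' Stands in for one subject's peripheral blood smear: a set of single-cell
#' crops of which exactly round(nCells x vacuolatedFraction) are vacuolated,
#' shuffled deterministically by the seed. Per-cell seeds derive from the
#' smear seed by a fixed counter scheme, so any cell can be regenerated
#' independently.
#'
#' @param nCells number of cells (>= 1).
#' @param vacuolatedFraction proportion in [0, 1].
#' @param params a \linkS4class{SyntheticParams}.
#' @param seed integer.
#' @param smearId identifier recorded in the manifest.
#' @return list with \code{cells} (list of \linkS4class{CellImage}) and
#'   \code{manifest} (data.frame: smear_id, cell_id, file, label, vacuole_count).
#' @export
generateSmear <- function(nCells, vacuolatedFraction, params = syntheticParams(),
                          seed = params@seed, smearId = "s1") {
  if (nCells < 1L) vqError("nCells must be >= 1", "vq_parameter_error")
  if (vacuolatedFraction < 0 || vacuolatedFraction > 1)
    vqError("vacuolatedFraction must lie in [0, 1]", "vq_parameter_error")
  nVac <- roundHalfUp(nCells * vacuolatedFraction)
  labels <- c(rep(TRUE, nVac), rep(FALSE, nCells - nVac))
  ord <- withSeed(seed, sample.int(nCells))
  labels <- labels[ord]
  cells <- vector("list", nCells)
  vacCounts <- integer(nCells)
  for (i in seq_len(nCells)) {
    cells[[i]] <- generateCell(params, vacuolated = labels[i],
                               seed = deriveSeed(seed, i))
    cells[[i]]@subjectId <- smearId
    vacCounts[i] <- .countComponents(cells[[i]]@vacuoleMask@grid)
  }
  cellIds <- sprintf("%s_c%03d", smearId, seq_len(nCells))
  manifest <- data.frame(
    smear_id = smearId, cell_id = cellIds,
    file = file.path(smearId, paste0(cellIds, ".png")),
    label = ifelse(labels, "vacuolated", "healthy"),
    vacuole_count = vacCounts, stringsAsFactors = FALSE)
  list(cells = cells, manifest = manifest)
}

## 4-connected component count via EBImage labelling
.countComponents <- function(grid) {
  if (!any(grid)) return(0L)
  lab <- EBImage::bwlabel(EBImage::Image(grid * 1))
  as.integer(max(lab))
}

#' Write a synthetic multi-smear dataset to disk
#'
#' Emulates a validation set of smears with known vacuolization fractions:
#' one directory per smear with 8-bit RGB PNG cell crops, grayscale PNG
#' ground-truth masks (cell/nucleus/vacuole) under \code{masks/}, and a
#' single manifest CSV. Re-running with identical arguments reproduces
#' identical files.
#'
#' @param nSmears number of smears.
#' @param fractions vacuolated fraction per smear (length nSmears).
#' @param params a \linkS4class{SyntheticParams}.
#' @param outDir output directory (created if missing).
#' @param cellsPerSmear cells per smear; default 30.
#' @param seed integer.
#' @return the manifest data.frame (with mask file columns), invisibly.
#' @export
generateDataset <- function(nSmears, fractions, params = syntheticParams(),
                            outDir, cellsPerSmear = 30L, seed = params@seed) {
  if (length(fractions) != nSmears)
    vqError("fractions must have one entry per smear", "vq_parameter_error")
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) vqError(sprintf("cannot create %s", outDir), "vq_io_error")
  manifests <- vector("list", nSmears)
  for (si in seq_len(nSmears)) {
    smearId <- sprintf("smear_%02d", si)
    sm <- generateSmear(cellsPerSmear, fractions[si], params,
                        seed = deriveSeed(seed, si * 100003L), smearId = smearId)
    sdir <- file.path(outDir, smearId)
    mdir <- file.path(sdir, "masks")
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    mf <- sm$manifest
    mf$cell_mask <- file.path(smearId, "masks", paste0(mf$cell_id, "_cell.png"))
    mf$nucleus_mask <- file.path(smearId, "masks", paste0(mf$cell_id, "_nucleus.png"))
    mf$vacuole_mask <- file.path(smearId, "masks", paste0(mf$cell_id, "_vacuole.png"))
    for (i in seq_along(sm$cells)) {
      cell <- sm$cells[[i]]
      writeImagePNG(cell, file.path(outDir, mf$file[i]))
      writeMaskPNG(cell@cellMask, file.path(outDir, mf$cell_mask[i]))
      writeMaskPNG(cell@nucleusMask, file.path(outDir, mf$nucleus_mask[i]))
      writeMaskPNG(cell@vacuoleMask, file.path(outDir, mf$vacuole_mask[i]))
    }
    manifests[[si]] <- mf
  }
  manifest <- do.call(rbind, manifests)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
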