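# Shared fixtures. Small geometries keep unit tests fast; the study-scale
# trained models used by the end-to-end checks are trained once per test run
# and cached here so several test files can reuse them.

tinyParams <- function(seed = 1L) syntheticParams(imageSize = 32L, seed = seed)

studyParams <- function(seed = 1L) syntheticParams(imageSize = 64L, seed = seed)

# quick low-capacity config for contract tests (not used for quality claims)
tinySegConfig <- function(target, seed = 1L, epochs = 2L)
  segTrainConfig(target, epochs = epochs, depth = 2L, baseFilters = 4L,
                 batchSize = 8L, seed = seed)

tinyClsConfig <- function(seed = 1L, epochs = 3L)
  clsTrainConfig(epochs = epochs, baseFilters = 4L, blocksPerStage = 1L,
                 batchSize = 16L, seed = seed)

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Study-scale fixtures mirroring the reproduction runs: 200-cell pool for
# segmentation, 400-cell balanced masked pool for classification, 64 px crops.
studySegPool <- function() cached("segPool", {
  generateCellPool(200L, studyParams(), seed = vacuoquant:::deriveSeed(1L, 12L))
})

studyCellBundle <- function() cached("cellBundle", {
  trainSegmenter(studySegPool(),
                 segTrainConfig("cell", seed = vacuoquant:::deriveSeed(1L, 1L)))
})

studyNucleusBundle <- function() cached("nucleusBundle", {
  trainSegmenter(studySegPool(),
                 segTrainConfig("nucleus", seed = vacuoquant:::deriveSeed(1L, 2L)))
})

studyClsBundle <- function() cached("clsBundle", {
  pool <- generateCellPool(400L, studyParams(), seed = vacuoquant:::deriveSeed(1L, 13L))
  trainClassifier(lapply(pool, maskWithTruth),
                  clsTrainConfig(seed = vacuoquant:::deriveSeed(1L, 3L)))
})

# trained full pipeline applied to the 8-smear ladder of known fractions
studyQuantification <- function() cached("quant", {
  dataDir <- file.path(tempdir(), "vq_accept_ds")
  mf <- generateDataset(8L, seq(0, 0.7, by = 0.1), studyParams(), dataDir,
                        cellsPerSmear = 30L, seed = vacuoquant:::deriveSeed(1L, 11L))
  quantifyDataset(mf, dataDir, studyCellBundle(), studyNucleusBundle(),
                  studyClsBundle(), decisionThreshold(0.65))
})

# brute-force Passing-Bablok oracle: enumerate every pairwise slope, apply the
# shifted-median rule directly (independent of the package implementation)
bruteForcePB <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) {
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      if (sl != -1) s <- c(s, sl)
    }
  }
  stopifnot(length(s) >= 1)
  K <- sum(s < -1)
  s <- sort(s)
  N <- length(s)
  slope <- if (N %% 2 == 1) s[(N + 1) / 2 + K] else (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
  list(slope = slope, intercept = median(y - slope * x))
}
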