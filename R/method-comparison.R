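#' @include AllClasses.R utils.R
NULL

## All pairwise slopes (y_j - y_i)/(x_j - x_i) over i < j, skipping ties in x
## and (per the Passing & Bablok 1983 convention) slopes exactly equal to -1;
## K counts slopes < -1. Shared by the estimator and the brute-force path.
.pbSlopes <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  s <- dy[keep] / dx[keep]
  s <- s[s != -1]
  s
}

.pbFitPoint <- function(x, y) {
  s <- .pbSlopes(x, y)
  N <- length(s)
  if (N < 1L) vqError("degenerate data: no valid pairwise slopes", "vq_degenerate_error")
  K <- sum(s < -1)
  s <- sort(s)
  slope <- if (N %% 2L == 1L) s[(N + 1L) %/% 2L + K]
           else mean(s[c(N %/% 2L + K, N %/% 2L + 1L + K)])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept, n = N)
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods, robust to
#' measurement error in both: the slope is the shifted median of all pairwise
#' slopes (y_j - y_i)/(x_j - x_i) over i < j with x_i != x_j — slopes equal
#' to -1 are excluded and the median index is offset by K, the number of
#' slopes below -1; for an even count the two middle order statistics after
#' the shift are averaged. The intercept is the median of y - slope * x.
#' 95% confidence intervals are percentile intervals over seeded bootstrap
#' resamples of the pairs (999 by default).
#'
#' @param data a \linkS4class{PairedMeasurements} with n >= 3 and x not all
#'   identical.
#' @param bootstrapSamples bootstrap resamples; default 999.
#' @param seed bootstrap seed.
#' @return a \linkS4class{PassingBablokFit}.
#' @examples
#' fit <- passingBablok(pairedMeasurements(1:10, 1:10), seed = 1)
#' fit@slope      # 1
#' fit@intercept  # 0
#' @export
passingBablok <- function(data, bootstrapSamples = 999L, seed = 1L) {
  x <- data@x; y <- data@y
  n <- length(x)
  if (n < 3L) vqError("Passing-Bablok requires n >= 3 pairs", "vq_parameter_error")
  fit <- .pbFitPoint(x, y)
  bs <- withSeed(seed, {
    out <- matrix(NA_real_, bootstrapSamples, 2L)
    for (b in seq_len(bootstrapSamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(.pbFitPoint(x[idx], y[idx]), vq_degenerate_error = function(e) NULL)
      if (!is.null(f)) out[b, ] <- c(f$slope, f$intercept)
    }
    out
  })
  ok <- stats::complete.cases(bs)
  if (!any(ok)) vqError("all bootstrap resamples degenerate", "vq_degenerate_error")
  sCI <- unname(stats::quantile(bs[ok, 1], c(0.025, 0.975)))
  iCI <- unname(stats::quantile(bs[ok, 2], c(0.025, 0.975)))
  new("PassingBablokFit", slope = fit$slope, intercept = fit$intercept,
      slopeCI = c(min(sCI[1], fit$slope), max(sCI[2], fit$slope)),
      interceptCI = c(min(iCI[1], fit$intercept), max(iCI[2], fit$intercept)),
      nPairwiseSlopes = as.integer(fit$n),
      bootstrapSamples = as.integer(bootstrapSamples), seed = as.integer(seed))
}

#' Bland-Altman agreement analysis
#'
#' Paired differences d_i = x_i - y_i; reports their mean, sample standard
#' deviation (n - 1 denominator) and the limits of agreement
#' mean +/- 1.96 SD.
#'
#' @param data a \linkS4class{PairedMeasurements} with n >= 2.
#' @return a \linkS4class{BlandAltmanResult}.
#' @export
blandAltman <- function(data) {
  d <- data@x - data@y
  if (length(d) < 2L) vqError("Bland-Altman requires n >= 2 pairs", "vq_parameter_error")
  m <- mean(d)
  s <- stats::sd(d)
  new("BlandAltmanResult", meanDifference = m, sdDifference = s,
      loa = c(m - 1.96 * s, m + 1.96 * s), n = length(d))
}

#' Pearson product-moment correlation of paired measurements
#'
#' @param data a \linkS4class{PairedMeasurements} with n >= 3 and both
#'   variables non-constant.
#' @return correlation in [-1, 1].
#' @export
pearsonR <- function(data) {
  x <- data@x; y <- data@y
  if (length(x) < 3L) vqError("Pearson correlation requires n >= 3", "vq_parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    vqError("correlation undefined for a constant variable", "vq_degenerate_error")
  stats::cor(x, y)
}

#' Levene's test of variance homogeneity
#'
#' Classic Levene W on absolute deviations from each group's mean:
#' W = ((N - k)/(k - 1)) * sum_i n_i (zbar_i - zbar)^2 / sum_ij (z_ij - zbar_i)^2
#' with z_ij = |v_ij - mean(v_i)|, referred to the F distribution with
#' (k - 1, N - k) degrees of freedom. Median centering (Brown-Forsythe) is
#' available as an option.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @param center "mean" (classic Levene, default) or "median" (Brown-Forsythe).
#' @return a \linkS4class{LeveneResult}.
#' @examples
#' leveneTest(list(a = c(1, 2, 4), b = c(2, 3, 9)))  # W ~ 4.129
#' @export
leveneTest <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    vqError("need at least two groups", "vq_parameter_error")
  if (any(vapply(groups, length, integer(1)) < 2L))
    vqError("every group needs at least two values", "vq_parameter_error")
  k <- length(groups)
  centerFun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(v) abs(v - centerFun(v)))
  ni <- lengths(z)
  N <- sum(ni)
  zi <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  between <- sum(ni * (zi - zbar)^2)
  within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), numeric(1)))
  if (within == 0)
    vqError("degenerate data: within-group deviations have no spread", "vq_degenerate_error")
  W <- (N - k) / (k - 1) * between / within
  p <- stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  new("LeveneResult", W = W, dfBetween = as.integer(k - 1L),
      dfWithin = as.integer(N - k), pValue = p, groupLabels = .groupLabels(groups))
}

.groupLabels <- function(groups) {
  if (!is.null(names(groups)) && all(nzchar(names(groups)))) names(groups)
  else sprintf("group%d", seq_along(groups))
}

#' Full comparison of automated vs manual quantification
#'
#' The manual consensus is the per-smear mean of the two manual analyses.
#' The report contains the Passing-Bablok fit of the automated percentages
#' against the consensus (consensus on the x axis as the reference method),
#' Bland-Altman for automated vs consensus and for the two manual raters
#' against each other, the Pearson correlation, and Levene's test on the
#' three paired-difference groups auto - manual1, auto - manual2,
#' manual1 - manual2. All differences run automated minus manual.
#' Degenerate sub-analyses (e.g. full agreement making the correlation or
#' Levene's test undefined) are flagged instead of raising.
#'
#' @param auto,manual1,manual2 equal-length numeric vectors of per-smear
#'   percentages.
#' @param bootstrapSamples for the Passing-Bablok CI; default 999.
#' @param seed bootstrap seed.
#' @return a \linkS4class{MethodComparisonResult}.
#' @export
compareMethods <- function(auto, manual1, manual2, bootstrapSamples = 999L, seed = 1L) {
  if (length(auto) != length(manual1) || length(auto) != length(manual2))
    vqError("auto, manual1 and manual2 must have equal length", "vq_parameter_error")
  consensus <- (manual1 + manual2) / 2
  flags <- character()
  degen <- function(what, expr) {
    tryCatch(expr, vq_degenerate_error = function(e) {
      flags <<- c(flags, what)
      NULL
    })
  }
  pb <- degen("passing_bablok", passingBablok(pairedMeasurements(consensus, auto),
                                              bootstrapSamples, seed))
  baAuto <- blandAltman(pairedMeasurements(auto, consensus))
  baManual <- blandAltman(pairedMeasurements(manual1, manual2))
  r <- degen("pearson", pearsonR(pairedMeasurements(auto, consensus)))
  lv <- degen("levene", leveneTest(list(
    auto_vs_manual1 = auto - manual1,
    auto_vs_manual2 = auto - manual2,
    manual1_vs_manual2 = manual1 - manual2)))
  new("MethodComparisonResult", passingBablok = pb, blandAltmanAuto = baAuto,
      blandAltmanManual = baManual, pearson = if (is.null(r)) NA_real_ else r,
      levene = lv, flags = flags)
}
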