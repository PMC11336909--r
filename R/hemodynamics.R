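## Hemodynamic analysis layer: percent change relative to a baseline
## window, ROI statistics for stimulation paradigms, and resting-state
## lag cross-correlation, shared by the blood-volume, blood-flow and
## oxygen-saturation time series.

#' Relative (percent) change of a time series
#'
#' r(t) = 100 (x(t) - m) / m with m the mean of the first \code{baselineN}
#' frames. The same formula serves the relative blood-volume, blood-flow
#' and oxygen-saturation series. The result is invariant to global scaling
#' of the series; a baseline mean at or below the numeric floor leaves the
#' series flagged undefined (all NA).
#'
#' @param series a \code{\link{timeSeries}} or numeric vector.
#' @param baselineN baseline window length (frames); taken from the
#'   \code{TimeSeries} when available.
#' @param framePeriod seconds per frame for plain vectors.
#' @return A \code{\link{RelativeSeries}}.
#' @examples
#' percentChange(relativeChange(c(rep(9.5, 10), 12.5)))[11]  # 31.6%
#' @export
relativeChange <- function(series, baselineN = 10L, framePeriod = 3.3) {
  if (is(series, "TimeSeries")) {
    x <- series@values
    baselineN <- series@baselineN
    framePeriod <- series@framePeriod
  } else x <- as.numeric(series)
  baselineN <- as.integer(baselineN)
  if (length(x) < baselineN)
    stop("series shorter than the baseline window")
  m <- mean(x[seq_len(baselineN)])
  if (!is.finite(m) || abs(m) < .Machine$double.eps * 100) {
    pct <- rep(NA_real_, length(x))
  } else {
    pct <- (x - m) / m * 100
  }
  new("RelativeSeries", percent = pct, baselineMean = m,
      framePeriod = framePeriod, sdPercent = numeric())
}

#' ROI-averaged time course of a map stack
#'
#' Per-frame mean over the ROI, with the per-frame across-pixel standard
#' deviation for shaded uncertainty bands.
#'
#' @param stack numeric array (depth x lateral x time).
#' @param roiMask logical matrix congruent with the maps.
#' @param framePeriod seconds per frame.
#' @param baselineN baseline window for downstream relative change.
#' @return A \code{\link{TimeSeries}} whose \code{sdValues} carry the
#'   across-pixel sd per frame.
#' @export
roiTimecourse <- function(stack, roiMask, framePeriod = 3.3,
                          baselineN = 10L) {
  d <- dim(stack)
  if (!any(roiMask)) stop("ROI mask is empty")
  if (!identical(dim(roiMask), d[1:2]))
    stop("ROI mask must match the map dimensions")
  M <- matrix(stack, d[1] * d[2], d[3])[as.vector(roiMask), , drop = FALSE]
  mu <- colMeans(M)
  sdv <- if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, d[3])
  timeSeries(mu, framePeriod = framePeriod, baselineN = baselineN,
             sdValues = sdv)
}

#' ROI-averaged relative-change time course
#'
#' Matches the analysis order of operations: the percent change is computed
#' per pixel first, then averaged over the ROI, with the across-pixel sd of
#' those pixel-level relative changes as the band.
#'
#' @param stack numeric array (depth x lateral x time).
#' @param roiMask logical matrix.
#' @param baselineN baseline window (frames).
#' @param framePeriod seconds per frame.
#' @return A \code{\link{RelativeSeries}} with \code{sdPercent} filled.
#' @export
roiRelativeTimecourse <- function(stack, roiMask, baselineN = 10L,
                                  framePeriod = 3.3) {
  d <- dim(stack)
  if (!any(roiMask)) stop("ROI mask is empty")
  M <- matrix(stack, d[1] * d[2], d[3])[as.vector(roiMask), , drop = FALSE]
  base <- rowMeans(M[, seq_len(baselineN), drop = FALSE])
  ok <- abs(base) > .Machine$double.eps * 100
  R <- (M[ok, , drop = FALSE] / base[ok] - 1) * 100
  if (!nrow(R)) stop("all ROI pixels have undefined (zero) baselines")
  new("RelativeSeries", percent = colMeans(R),
      baselineMean = mean(base[ok]), framePeriod = framePeriod,
      sdPercent = if (nrow(R) > 1) apply(R, 2, stats::sd) else
        rep(0, d[3]))
}

# Pearson correlation of a reference series against the rows of a matrix,
# at one integer lag, over the truncated overlap window.
.lagCor <- function(ref, M, lag) {
  n <- length(ref)
  if (lag >= 0) {
    a <- ref[seq_len(n - lag)]
    B <- M[, (1 + lag):n, drop = FALSE]
  } else {
    a <- ref[(1 - lag):n]
    B <- M[, seq_len(n + lag), drop = FALSE]
  }
  a <- a - mean(a)
  B <- B - rowMeans(B)
  num <- as.numeric(B %*% a)
  den <- sqrt(sum(a^2) * rowSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Voxel-wise lagged cross-correlation against a reference ROI
#'
#' The reference is the ROI-mean series; every voxel's series is Pearson-
#' correlated with it at each integer lag in [-maxLag, maxLag], both series
#' mean-removed over the truncated overlap window (no zero padding, so R
#' does not decay artificially with lag). Positive lag means the voxel lags
#' the reference. Zero-variance voxels are NA.
#'
#' @param stack numeric array (depth x lateral x time).
#' @param refMask logical matrix defining the reference ROI.
#' @param maxLag maximum lag in frames; stack length must exceed 2 maxLag.
#' @param framePeriod seconds per frame (lag axis scaling).
#' @return A \code{\link{CrossCorrResult}} with R of dim (depth, lateral,
#'   lag).
#' @export
crosscorrMap <- function(stack, refMask, maxLag, framePeriod = 0.71) {
  d <- dim(stack)
  if (d[3] <= 2 * maxLag)
    stop("stack length must exceed twice the maximum lag")
  if (!any(refMask)) stop("reference ROI mask is empty")
  M <- matrix(stack, d[1] * d[2], d[3])
  ref <- colMeans(M[as.vector(refMask), , drop = FALSE])
  lags <- (-maxLag):maxLag
  R <- array(NA_real_, dim = c(d[1], d[2], length(lags)))
  for (k in seq_along(lags))
    R[, , k] <- matrix(.lagCor(ref, M, lags[k]), d[1], d[2])
  new("CrossCorrResult", R = R, lags = as.integer(lags),
      framePeriod = framePeriod)
}

#' Lagged cross-correlation between two ROI-mean series
#'
#' Pearson correlation of the ROI-A mean against the ROI-B mean at each
#' lag; positive lag means B lags A. Peak and trough lags are attached as
#' attributes \code{peakLag} and \code{troughLag} (seconds).
#'
#' @param stack numeric array (depth x lateral x time).
#' @param roiA,roiB logical masks.
#' @param maxLag maximum lag, frames.
#' @param framePeriod seconds per frame.
#' @return A \code{\link{CrossCorrResult}} with R of dim (1, 1, lag).
#' @export
roiPairCrosscorr <- function(stack, roiA, roiB, maxLag,
                             framePeriod = 0.71) {
  d <- dim(stack)
  if (d[3] <= 2 * maxLag)
    stop("stack length must exceed twice the maximum lag")
  if (!any(roiA) || !any(roiB)) stop("ROI masks must be non-empty")
  M <- matrix(stack, d[1] * d[2], d[3])
  a <- colMeans(M[as.vector(roiA), , drop = FALSE])
  b <- colMeans(M[as.vector(roiB), , drop = FALSE])
  lags <- (-maxLag):maxLag
  r <- vapply(lags, function(l)
    .lagCor(a, matrix(b, 1), l), numeric(1))
  res <- new("CrossCorrResult",
             R = array(r, dim = c(1L, 1L, length(lags))),
             lags = as.integer(lags), framePeriod = framePeriod)
  attr(res, "peakLag") <- lags[which.max(r)] * framePeriod
  attr(res, "troughLag") <- lags[which.min(r)] * framePeriod
  res
}

#' Window summary of a relative series under a stimulation paradigm
#'
#' Means over the baseline, stimulation and post-stimulation windows, plus
#' the location of the series peak relative to stimulus onset.
#'
#' @param rel a \code{\link{RelativeSeries}} (or \code{TimeSeries}).
#' @param paradigm a \code{\link{stimulusParadigm}}.
#' @return list: \code{baselineMean}, \code{stimulusMean}, \code{postMean}
#'   (same units as the series), \code{peakValue}, \code{peakTime} (seconds
#'   from stimulus onset), \code{label}.
#' @export
paradigmSummary <- function(rel, paradigm = stimulusParadigm()) {
  validObject(paradigm)
  x <- if (is(rel, "RelativeSeries")) rel@percent else rel@values
  dt <- rel@framePeriod
  total <- paradigm@baseline + paradigm@stimulusOn + paradigm@post
  n <- length(x)
  if (n * dt < total - dt / 2)
    stop("series (", round(n * dt, 2), " s) shorter than the paradigm (",
         total, " s)")
  tmid <- (seq_len(n) - 0.5) * dt
  inBase <- tmid < paradigm@baseline
  inStim <- tmid >= paradigm@baseline &
    tmid < paradigm@baseline + paradigm@stimulusOn
  inPost <- tmid >= paradigm@baseline + paradigm@stimulusOn & tmid < total
  pk <- which.max(x)
  list(baselineMean = mean(x[inBase]), stimulusMean = mean(x[inStim]),
       postMean = mean(x[inPost]), peakValue = x[pk],
       peakTime = tmid[pk] - paradigm@baseline, label = paradigm@label)
}
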