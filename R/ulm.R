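## Ultrasound localization microscopy: sub-pixel microbubble localization
## (regional maxima refined by a log-Gaussian three-point fit, exact for a
## Gaussian point-spread function), Hungarian frame-to-frame track linking,
## and accumulation of the tracks onto a super-resolution grid (default
## 10 um) as density, direction-coded and mean-speed maps.

#' Localize microbubbles in one frame to sub-pixel precision
#'
#' Candidate detections are strict regional maxima of the amplitude frame
#' above the detection threshold; each is refined independently along depth
#' and lateral axes by the three-point log-Gaussian interpolation, which is
#' exact for a Gaussian PSF. Returns an empty set when nothing exceeds the
#' threshold.
#'
#' @param frame numeric matrix, non-negative amplitude (envelope) image.
#' @param detectionThreshold absolute amplitude threshold; NULL takes
#'   \code{noiseFloorMult} times the frame's median absolute amplitude.
#' @param noiseFloorMult noise-floor multiple for the default threshold.
#' @return data.frame: \code{z}, \code{x} (continuous pixel units),
#'   \code{amp}.
#' @examples
#' tr <- trackSet(list(data.frame(frame = 1, z = 10.3, x = 20.7)))
#' f <- simulateMbMovie(tr, psfSigma = 1.5, frameShape = c(32, 32))$frames
#' localizeMbs(f[, , 1], detectionThreshold = 0.5)
#' @export
localizeMbs <- function(frame, detectionThreshold = NULL,
                        noiseFloorMult = 6) {
  nz <- nrow(frame); nx <- ncol(frame)
  if (is.null(detectionThreshold))
    detectionThreshold <- noiseFloorMult *
      stats::median(abs(frame)) + .Machine$double.eps
  if (nz < 3L || nx < 3L)
    return(data.frame(z = numeric(0), x = numeric(0), amp = numeric(0)))
  inner <- frame[2:(nz - 1), 2:(nx - 1)]
  isMax <- inner > detectionThreshold
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    shifted <- frame[(2 + dz):(nz - 1 + dz), (2 + dx):(nx - 1 + dx)]
    # ties (a peak exactly between two pixels) are broken by scan order so
    # each plateau yields exactly one detection
    isMax <- isMax & if (dx > 0 || (dx == 0 && dz > 0))
      inner > shifted else inner >= shifted
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(z = numeric(0), x = numeric(0), amp = numeric(0)))
  zi <- idx[, 1] + 1L
  xi <- idx[, 2] + 1L
  refine <- function(fm, f0, fp) {
    ok <- fm > 0 & f0 > 0 & fp > 0
    den <- 2 * (2 * log(f0) - log(fm) - log(fp))
    delta <- ifelse(ok & den > 0, (log(fp) - log(fm)) / den, 0)
    pmin(pmax(delta, -0.5), 0.5)
  }
  # marginal sums over the 3x3 patch: for a separable Gaussian PSF the
  # marginal along one axis is itself Gaussian, so the three-point
  # log-quadratic fit stays exact while averaging noise over 3 pixels
  msum <- function(dzo, dxo) {
    acc <- 0
    for (o in -1:1)
      acc <- acc + if (is.null(dzo)) frame[cbind(zi + o, xi + dxo)] else
        frame[cbind(zi + dzo, xi + o)]
    acc
  }
  dz <- refine(msum(-1L, NULL), msum(0L, NULL), msum(1L, NULL))
  dx <- refine(msum(NULL, -1L), msum(NULL, 0L), msum(NULL, 1L))
  data.frame(z = zi + dz, x = xi + dx, amp = frame[cbind(zi, xi)])
}

#' Link per-frame localizations into tracks
#'
#' Frame-to-frame association minimizes total Euclidean displacement via
#' optimal bipartite (Hungarian) assignment; candidate pairs farther apart
#' than \code{maxLinkDistance} are forbidden, unmatched detections open new
#' tracks, unmatched tracks terminate (no gap closing by default), and
#' tracks shorter than \code{minTrackLength} frames are discarded.
#'
#' @param detections list of per-frame data.frames from
#'   \code{\link{localizeMbs}} (index = frame number), or a single
#'   data.frame with a \code{frame} column.
#' @param maxLinkDistance maximum per-frame displacement, pixels.
#' @param maxGap frames of allowed gap (only 0 supported).
#' @param minTrackLength minimum surviving track length in frames.
#' @param framePeriod seconds per frame.
#' @param pixelPitch mm per pixel.
#' @return A \code{\link{TrackSet}}.
#' @export
linkTracks <- function(detections, maxLinkDistance = 2,
                       maxGap = 0L, minTrackLength = 20L,
                       framePeriod = 1.4e-3, pixelPitch = 0.1) {
  if (maxGap != 0L) stop("gap closing is not supported (maxGap must be 0)")
  if (is.data.frame(detections)) {
    nf <- max(detections$frame)
    detections <- lapply(seq_len(nf), function(f)
      detections[detections$frame == f, c("z", "x", "amp"), drop = FALSE])
  }
  BIG <- 1e9
  open <- list()     # active tracks: data.frames frame/z/x/amp
  done <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nDet <- if (is.null(det)) 0L else nrow(det)
    nOpen <- length(open)
    assigned <- integer(0)
    if (nOpen > 0L && nDet > 0L) {
      last <- t(vapply(open, function(tr)
        c(tr$z[nrow(tr)], tr$x[nrow(tr)]), numeric(2)))
      D <- sqrt(outer(last[, 1], det$z, "-")^2 +
                  outer(last[, 2], det$x, "-")^2)
      C <- matrix(BIG, nOpen + nDet, nOpen + nDet)
      Dg <- D
      Dg[Dg > maxLinkDistance] <- BIG
      C[seq_len(nOpen), seq_len(nDet)] <- Dg
      # diagonal "skip" costs let any row or column stay unmatched
      for (i in seq_len(nOpen)) C[i, nDet + i] <- maxLinkDistance
      for (j in seq_len(nDet)) C[nOpen + j, j] <- maxLinkDistance
      C[(nOpen + 1):(nOpen + nDet), (nDet + 1):(nDet + nOpen)] <- 0
      sol <- hungarianAssign(C)
      assigned <- integer(nDet)
      for (i in seq_len(nOpen)) {
        j <- sol[i]
        if (j <= nDet && D[i, j] <= maxLinkDistance) {
          open[[i]] <- rbind(open[[i]],
                             data.frame(frame = f, z = det$z[j],
                                        x = det$x[j], amp = det$amp[j]))
          assigned[j] <- i
        }
      }
      extended <- vapply(open, function(tr) tr$frame[nrow(tr)] == f,
                         logical(1))
      done <- c(done, open[!extended])
      open <- open[extended]
    } else if (nOpen > 0L) {
      done <- c(done, open)
      open <- list()
    }
    if (nDet > 0L) {
      newIdx <- which(if (length(assigned)) assigned == 0L else
        rep(TRUE, nDet))
      for (j in newIdx)
        open <- c(open, list(data.frame(frame = f, z = det$z[j],
                                        x = det$x[j], amp = det$amp[j])))
    }
  }
  done <- c(done, open)
  keep <- Filter(function(tr) nrow(tr) >= minTrackLength, done)
  trackSet(keep, framePeriod = framePeriod, pixelPitch = pixelPitch)
}

#' Accumulate tracks into super-resolved ULM maps
#'
#' Every localization increments its super-resolution bin of the density
#' map; per-step speeds (displacement times frame rate) are averaged into
#' the bins their endpoint localizations occupy; the direction-coded map is
#' the density signed by each track's net depth displacement (+ descending,
#' deeper over time).
#'
#' @param tracks a \code{\link{TrackSet}} (positions in pixel units).
#' @param gridPitch super-resolution bin size, mm (default 0.01 = 10 um).
#' @param frameShape original frame size in pixels, used to size the grid.
#' @return A \code{\link{ULMMaps}}.
#' @export
accumulateMaps <- function(tracks, gridPitch = 0.01, frameShape) {
  if (gridPitch <= 0) stop("gridPitch must be positive")
  if (!length(tracks@tracks)) stop("track set is empty")
  pitch <- tracks@pixelPitch
  rate <- 1 / tracks@framePeriod
  nzb <- ceiling(frameShape[1] * pitch / gridPitch)
  nxb <- ceiling(frameShape[2] * pitch / gridPitch)
  density <- matrix(0, nzb, nxb)
  signedDen <- matrix(0, nzb, nxb)
  speedSum <- matrix(0, nzb, nxb)
  speedN <- matrix(0, nzb, nxb)
  # pixel k has its center at (k-1)*pitch mm; bins tile that axis
  for (tr in tracks@tracks) {
    n <- nrow(tr)
    dirSign <- sign(tr$z[n] - tr$z[1])
    if (dirSign == 0) dirSign <- 0
    bz <- pmin(pmax(floor((tr$z - 1) * pitch / gridPitch) + 1L, 1L), nzb)
    bx <- pmin(pmax(floor((tr$x - 1) * pitch / gridPitch) + 1L, 1L), nxb)
    for (k in seq_len(n)) {
      density[bz[k], bx[k]] <- density[bz[k], bx[k]] + 1
      signedDen[bz[k], bx[k]] <- signedDen[bz[k], bx[k]] + dirSign
    }
    if (n > 1L) {
      stepSpeed <- sqrt(diff(tr$z)^2 + diff(tr$x)^2) * pitch * rate  # mm/s
      for (k in seq_len(n - 1L)) {
        for (cell in unique(list(c(bz[k], bx[k]), c(bz[k + 1], bx[k + 1])))) {
          speedSum[cell[1], cell[2]] <- speedSum[cell[1], cell[2]] +
            stepSpeed[k]
          speedN[cell[1], cell[2]] <- speedN[cell[1], cell[2]] + 1
        }
      }
    }
  }
  meanSpeed <- matrix(NA_real_, nzb, nxb)
  hasSpeed <- speedN > 0
  meanSpeed[hasSpeed] <- speedSum[hasSpeed] / speedN[hasSpeed]
  meanSpeed[density == 0] <- NA_real_
  new("ULMMaps", density = density, directionCoded = signedDen,
      meanSpeed = meanSpeed, gridPitch = gridPitch)
}

#' Full ULM chain on a microbubble frame stack
#'
#' Per-frame localization, Hungarian linking, and accumulation. SVD
#' filtering of the raw IQ (when starting from IQ data) reuses
#' \code{\link{svdClutterFilter}} with its own rejection count (default 5).
#'
#' @param frames numeric array (depth x lateral x time) of amplitude
#'   frames, or an \code{\link{IQMovie}} (then SVD-filtered and enveloped
#'   first).
#' @param detectionThreshold see \code{\link{localizeMbs}}.
#' @param maxLinkDistance,minTrackLength see \code{\link{linkTracks}}.
#' @param gridPitch see \code{\link{accumulateMaps}}.
#' @param framePeriod seconds per frame.
#' @param pixelPitch mm per pixel.
#' @param svdNReject rejection count when input is IQ.
#' @return list: \code{tracks} (\code{TrackSet}), \code{maps}
#'   (\code{ULMMaps} or NULL when no track survives).
#' @export
ulmPipeline <- function(frames, detectionThreshold = NULL,
                        maxLinkDistance = 2, minTrackLength = 20L,
                        gridPitch = 0.01, framePeriod = 1.4e-3,
                        pixelPitch = 0.1, svdNReject = 5L) {
  if (is(frames, "IQMovie")) {
    framePeriod <- 1 / frames@prfc
    pixelPitch <- frames@pixelPitch
    filt <- svdClutterFilter(frames, svdNReject)$movie
    frames <- Mod(filt@data)
  }
  nt <- dim(frames)[3]
  dets <- lapply(seq_len(nt), function(f)
    localizeMbs(frames[, , f], detectionThreshold))
  tr <- linkTracks(dets, maxLinkDistance = maxLinkDistance,
                   minTrackLength = minTrackLength,
                   framePeriod = framePeriod, pixelPitch = pixelPitch)
  maps <- if (length(tr@tracks))
    accumulateMaps(tr, gridPitch, frameShape = dim(frames)[1:2]) else NULL
  list(tracks = tr, maps = maps)
}

#' Export a track table as CSV
#'
#' @param tracks a \code{\link{TrackSet}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportTracks <- function(tracks, path) {
  rows <- lapply(seq_along(tracks@tracks), function(i) {
    tr <- tracks@tracks[[i]]
    sp <- c(NA, sqrt(diff(tr$z)^2 + diff(tr$x)^2) * tracks@pixelPitch /
              tracks@framePeriod)
    data.frame(track = i, frame = tr$frame, z = tr$z, x = tr$x,
               stepSpeed = sp)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
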