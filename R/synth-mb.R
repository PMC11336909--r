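## Synthetic microbubble movies: sparse isotropic-Gaussian point-spread
## functions rendered at continuous track positions plus white noise.

#' Simulate a microbubble frame stack from ground-truth tracks
#'
#' Each frame is the sum of isotropic Gaussian point-spread functions
#' centered at the continuous (sub-pixel) positions of the tracks alive in
#' that frame, plus additive Gaussian noise.
#'
#' @param tracks a \code{\link{trackSet}}: ground-truth trajectories in
#'   continuous pixel units (1-based grid, position (1, 1) is the first
#'   pixel center).
#' @param psfSigma Gaussian PSF standard deviation in pixels (> 0).
#' @param frameShape integer(2), (depth, lateral) pixels.
#' @param nFrames number of frames; defaults to the largest frame index in
#'   the tracks.
#' @param noiseSigma additive noise sd, in units of the unit PSF peak.
#' @param seed integer seed.
#' @return list: \code{frames} (numeric array depth x lateral x time) and
#'   \code{truth} (the input \code{TrackSet}).
#' @examples
#' tr <- trackSet(list(data.frame(frame = 1:3, z = 10.3, x = 20.7)))
#' mv <- simulateMbMovie(tr, psfSigma = 1.5, frameShape = c(32, 32))
#' which(mv$frames[, , 1] == max(mv$frames[, , 1]), arr.ind = TRUE)
#' @export
simulateMbMovie <- function(tracks, psfSigma = 1.5, frameShape = c(64, 64),
                            nFrames = NULL, noiseSigma = 0, seed = 1L) {
  if (psfSigma <= 0) stop("psfSigma must be positive")
  validObject(tracks)
  nz <- frameShape[1]; nx <- frameShape[2]
  trs <- tracks@tracks
  maxFrame <- if (length(trs)) max(vapply(trs, function(t) max(t$frame),
                                          numeric(1))) else 1
  nFrames <- as.integer(nFrames %||% maxFrame)
  for (tr in trs)
    if (any(tr$z < 1 | tr$z > nz | tr$x < 1 | tr$x > nx))
      stop("track positions must lie within the frame bounds")
  .withSeed(seed, {
    frames <- array(0, dim = c(nz, nx, nFrames))
    win <- ceiling(4 * psfSigma)
    for (tr in trs) {
      for (k in seq_len(nrow(tr))) {
        fr <- tr$frame[k]
        if (fr < 1L || fr > nFrames) next
        z0 <- tr$z[k]; x0 <- tr$x[k]; a <- tr$amp[k]
        zi <- max(1L, floor(z0) - win):min(nz, ceiling(z0) + win)
        xi <- max(1L, floor(x0) - win):min(nx, ceiling(x0) + win)
        psf <- a * exp(-(outer((zi - z0)^2, (xi - x0)^2, "+")) /
                         (2 * psfSigma^2))
        frames[zi, xi, fr] <- frames[zi, xi, fr] + psf
      }
    }
    if (noiseSigma > 0)
      frames <- frames + array(stats::rnorm(length(frames), sd = noiseSigma),
                               dim = dim(frames))
    list(frames = frames, truth = tracks)
  })
}

#' Build straight constant-velocity ground-truth tracks
#'
#' Convenience constructor of linear tracks for simulator studies.
#'
#' @param start numeric(2), (z, x) starting position in pixels.
#' @param step numeric(2), per-frame displacement in pixels.
#' @param nSteps number of frames in the track.
#' @param startFrame first frame index.
#' @return A data.frame usable inside \code{\link{trackSet}}.
#' @export
linearTrack <- function(start, step, nSteps, startFrame = 1L) {
  k <- 0:(nSteps - 1)
  data.frame(frame = startFrame + k,
             z = start[1] + k * step[1],
             x = start[2] + k * step[2],
             amp = rep(1, nSteps))
}
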