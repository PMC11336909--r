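## Power-Doppler blood-volume mapping: after clutter rejection the per-pixel
## mean squared IQ magnitude is proportional to the fractional moving blood
## volume (red blood cells are the dominant scatterers), so the power
## Doppler intensity map is taken as the CBV map.

#' Power-Doppler intensity (CBV) map
#'
#' intensity(z, x) = mean over slow time of |IQ(z, x, t)|^2. The input is
#' expected to be clutter-filtered already (not enforced). An optional
#' Gaussian smoothing is available behind a flag; none is applied by
#' default, keeping the estimator minimal.
#'
#' @param movie an \code{\link{IQMovie}} (clutter-filtered).
#' @param smoothSigma Gaussian smoothing sd in pixels; 0 disables.
#' @return A \code{\link{CBVMap}}. The dB view (via
#'   \code{\link{intensityDb}}) is referenced to the map maximum.
#' @examples
#' m <- IQMovie(array(complex(modulus = 1,
#'                            argument = runif(32, 0, 2 * pi)),
#'                    dim = c(4, 4, 2)))
#' intensity(powerDopplerMap(m))[1, 1]  # unit-magnitude phasor -> 1
#' @export
powerDopplerMap <- function(movie, smoothSigma = 0) {
  d <- dim(movie@data)
  if (d[3] < 1L) stop("movie has zero frames")
  p <- matrix(rowMeans(Mod(.casorati(movie@data))^2), d[1], d[2])
  if (smoothSigma > 0) p <- .gaussSmooth(p, smoothSigma)
  new("CBVMap", intensity = p, nFramesUsed = as.integer(d[3]))
}

# Separable Gaussian smoothing with reflected edges.
.gaussSmooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(v[r:1], v, v[n:(n - r + 1)])
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}
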