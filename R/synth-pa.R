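## Synthetic multispectral photoacoustic stacks generated from ground-truth
## chromophore concentration maps under the linear absorption model
##   p_lambda(z, x) = E_lambda * fluence(z) * sum_k eps_k(lambda) c_k(z, x)
## with exponential depth-dependent fluence and additive Gaussian noise.

#' Simulate a multispectral photoacoustic stack
#'
#' @param phantom a \code{\link{chromophorePhantom}} with ground-truth HbO,
#'   HbD and ICG concentration maps.
#' @param wavelengths nm; must all be present in the extinction table.
#' @param pulseEnergies mJ per wavelength.
#' @param nSets number of repeated wavelength sets, each with independent
#'   noise.
#' @param seed integer seed.
#' @return list: \code{stack} (a \code{\link{PAStack}}) and \code{truth}
#'   (the phantom).
#' @examples
#' ph <- chromophorePhantom(hbo = matrix(1, 8, 8), hbd = matrix(0, 8, 8),
#'                          icg = matrix(0, 8, 8))
#' simulateMspaStack(ph)$stack
#' @export
simulateMspaStack <- function(phantom, wavelengths = c(750, 800, 850),
                              pulseEnergies = c(1, 1, 1), nSets = 5L,
                              seed = 1L) {
  validObject(phantom)
  eps <- extinctionCoefficients(wavelengths)     # errors on unknown lambda
  nz <- nrow(phantom@hbo); nx <- ncol(phantom@hbo)
  fluence <- exp(-phantom@fluenceDecay * (seq_len(nz) - 1) *
                   phantom@pixelPitch)
  conc <- cbind(as.vector(phantom@hbo), as.vector(phantom@hbd),
                as.vector(phantom@icg))
  .withSeed(seed, {
    images <- array(0, dim = c(nz, nx, length(wavelengths), nSets))
    for (w in seq_along(wavelengths)) {
      clean <- matrix(conc %*% eps[w, ], nz, nx) * fluence *
        pulseEnergies[w]
      for (s in seq_len(nSets)) {
        noisy <- clean
        if (phantom@noiseSigma > 0)
          noisy <- noisy + matrix(stats::rnorm(nz * nx,
                                               sd = phantom@noiseSigma),
                                  nz, nx)
        images[, , w, s] <- noisy
      }
    }
    list(stack = PAStack(images, wavelengths, pulseEnergies,
                         pixelPitch = phantom@pixelPitch),
         truth = phantom)
  })
}

#' Two-tube phantom scene: flowing blood and static indocyanine green
#'
#' Builds the validation scene used throughout the package's end-to-end
#' tests: a left tube of circulating blood whose oxy/deoxy-hemoglobin split
#' is set by \code{so2Level}, and a right tube of static ICG in water. The
#' returned vessel list drives the IQ simulator (axial flow in the left
#' tube) and the phantom drives the photoacoustic simulator.
#'
#' @param so2Level blood oxygen saturation in the left tube, in [0, 1].
#' @param icgConcentration ICG amount in the right tube (arbitrary units).
#' @param flowSpeed axial blood speed in the left tube, mm/s (signed,
#'   + descending).
#' @param shape integer(2), (depth, lateral) pixels of the scene.
#' @param pixelPitch mm per pixel.
#' @param tubeRadius inner tube radius, mm.
#' @param hbTotal total hemoglobin amount in the blood tube.
#' @param fluenceDecay effective fluence attenuation, 1/mm.
#' @param noiseSigma photoacoustic noise sd.
#' @return list: \code{vessels} (list of \code{VesselSpec}) and
#'   \code{phantom} (a \code{ChromophorePhantom}).
#' @examples
#' sc <- makeTubePhantomScene(so2Level = 0.66)
#' range(sc$phantom@hbo / pmax(sc$phantom@hbo + sc$phantom@hbd, 1e-12))
#' @export
makeTubePhantomScene <- function(so2Level = 0.9, icgConcentration = 1,
                                 flowSpeed = 10, shape = c(64, 64),
                                 pixelPitch = 0.1, tubeRadius = 0.785,
                                 hbTotal = 1, fluenceDecay = 0,
                                 noiseSigma = 0) {
  if (so2Level < 0 || so2Level > 1) stop("so2Level must lie in [0, 1]")
  nz <- shape[1]; nx <- shape[2]
  zc <- (nz / 2) * pixelPitch
  xLeft <- (nx / 4) * pixelPitch
  xRight <- (3 * nx / 4) * pixelPitch
  leftTube <- vesselSpec(center = c(zc, xLeft), radius = tubeRadius,
                         axialVelocity = flowSpeed, orientation = "axial")
  rmask <- function(xc) {
    g <- .gridMm(nz, nx, pixelPitch)
    dz <- outer(g$z - zc, rep(1, nx))
    dx <- outer(rep(1, nz), g$x - xc)
    abs(dx) <= tubeRadius & abs(dz) <= 3 * tubeRadius
  }
  leftMask <- rmask(xLeft)
  rightMask <- rmask(xRight)
  hboMap <- matrix(0, nz, nx); hbdMap <- matrix(0, nz, nx)
  icgMap <- matrix(0, nz, nx)
  hboMap[leftMask] <- hbTotal * so2Level
  hbdMap[leftMask] <- hbTotal * (1 - so2Level)
  icgMap[rightMask] <- icgConcentration
  phantom <- chromophorePhantom(hboMap, hbdMap, icgMap,
                                fluenceDecay = fluenceDecay,
                                noiseSigma = noiseSigma,
                                pixelPitch = pixelPitch)
  list(vessels = list(leftTube), phantom = phantom,
       bloodMask = leftMask, icgMask = rightMask)
}
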