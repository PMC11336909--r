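## Synthetic beamformed-IQ movie generator. Simulation is at the
## compounded-IQ level (beamforming is vendor-side): blood speckle is a sum
## of per-scatterer complex Gaussian amplitudes with a deterministic phase
## advance per frame given by the Doppler relation f_d = -2 f0 v_z / c
## (descending flow, away from the transducer, produces a negative Doppler
## shift), and tissue clutter is an exact low-rank sum of smooth spatial
## patterns times band-limited temporal envelopes.

# Pixel-center coordinates in mm for a (nz, nx) grid.
.gridMm <- function(nz, nx, pitch) {
  list(z = (seq_len(nz) - 1) * pitch, x = (seq_len(nx) - 1) * pitch)
}

# Distance from the vessel axis for points (z, x) in mm.
.vesselRadialDist <- function(vessel, z, x) {
  dz <- z - vessel@center[1]
  dx <- x - vessel@center[2]
  if (vessel@orientation == "axial") {
    abs(dx)
  } else if (vessel@orientation == "lateral") {
    abs(dz)
  } else {
    th <- vessel@angle * pi / 180
    abs(-dz * sin(th) + dx * cos(th))
  }
}

# Local flow speed at radial distance r from the axis.
.profileVelocity <- function(vessel, r) {
  if (vessel@profile == "parabolic")
    vessel@axialVelocity * pmax(1 - (r / vessel@radius)^2, 0)
  else vessel@axialVelocity + 0 * r
}

# Logical mask of pixels inside a vessel.
.vesselMask <- function(vessel, nz, nx, pitch) {
  g <- .gridMm(nz, nx, pitch)
  dz <- outer(g$z - vessel@center[1], rep(1, nx))
  dx <- outer(rep(1, nz), g$x - vessel@center[2])
  r <- vessel@radius
  halfLen <- 3 * r
  if (vessel@orientation == "axial") {
    abs(dx) <= r & abs(dz) <= halfLen
  } else if (vessel@orientation == "lateral") {
    abs(dz) <= r & abs(dx) <= halfLen
  } else {
    th <- vessel@angle * pi / 180
    along <- dz * cos(th) + dx * sin(th)
    across <- -dz * sin(th) + dx * cos(th)
    abs(across) <= r & abs(along) <= halfLen
  }
}

# Smooth complex random spatial field (Gaussian-smoothed complex noise),
# unit RMS; independent draws are near-orthogonal, so a sum of nModes
# field-times-envelope products has nModes well-separated singular values.
.smoothField <- function(nz, nx, smoothSigma = 3) {
  f <- .gaussSmooth(matrix(stats::rnorm(nz * nx), nz, nx), smoothSigma) +
    1i * .gaussSmooth(matrix(stats::rnorm(nz * nx), nz, nx), smoothSigma)
  f / sqrt(mean(Mod(f)^2))
}

# Band-limited complex temporal envelope, unit RMS: a sum of random
# phasors with frequencies drawn uniformly on [-bw, bw]. The support is a
# hard band edge - tissue motion has no energy beyond its bandwidth - so
# clutter and blood Doppler bands can be made exactly disjoint. Works at
# any bw, including bandwidths below the ensemble's Fourier resolution.
# Note the realizable rank of a bw-limited process over a window of T
# seconds is about 2*bw*T + 1 temporal degrees of freedom.
.bandlimitedEnvelope <- function(nt, prf, bw, nComp = 32L) {
  fj <- stats::runif(nComp, -bw, bw)
  aj <- .cnoise(nComp, sqrt(0.5))
  tt <- (0:(nt - 1)) / prf
  env <- as.vector(exp(2i * pi * outer(tt, fj)) %*% aj)
  env / sqrt(mean(Mod(env)^2))
}

#' Simulate a beamformed complex IQ movie with known ground truth
#'
#' Generates blood speckle inside the given vessels (per-scatterer complex
#' Gaussian amplitudes advancing in phase at the Doppler frequency of the
#' vessel's axial velocity, with a small fractional frequency spread across
#' scatterers emulating intravascular velocity dispersion), an exact
#' rank-limited tissue-clutter process, and additive complex white noise.
#'
#' Clutter amplitude and the noise level are specified relative to the blood
#' speckle RMS (or absolutely when the scene has no vessels).
#'
#' @param vessels list of \code{\link{vesselSpec}} objects (may be empty).
#' @param clutter a \code{\link{clutterSpec}} or NULL for no clutter.
#' @param shape integer(3), (depth, lateral, slow-time) dimensions.
#' @param pixelPitch mm per pixel.
#' @param f0 center frequency, Hz.
#' @param c sound speed, m/s.
#' @param prfc compounded frame rate, Hz.
#' @param noiseSigma additive complex-noise sd per component, in units of
#'   the blood speckle RMS (default 3e-4, a noise floor 70 dB below blood,
#'   representative of well-compounded plane-wave data through a cranial
#'   window).
#' @param velocitySpread fractional sd of per-scatterer Doppler frequency
#'   about the vessel's nominal value.
#' @param speckleTau blood speckle decorrelation time, seconds; scatterer
#'   amplitudes fluctuate with a Gaussian-shaped spectrum of sd
#'   1/(2 pi speckleTau) Hz, emulating out-of-plane and transverse
#'   decorrelation without heavy spectral tails.
#' @param axialPsfSigma axial extent (Gaussian sd, mm) of the beamformed
#'   point-spread function used to render each scatterer.
#' @param seed integer seed; identical seeds give identical movies.
#' @return A list with elements \code{movie} (an \code{\link{IQMovie}}) and
#'   \code{truth}: per-pixel ground-truth signed axial velocity (mm/s,
#'   + descending), Doppler modulation frequency (Hz), blood mask, blood
#'   speckle RMS, the clutter-only and blood-only movies, and an
#'   \code{aliased} flag set when any vessel's Doppler frequency exceeds
#'   +/- prfc/2.
#' @examples
#' sc <- simulateIQMovie(list(vesselSpec(c(2, 2), 0.3, 10)),
#'                       clutterSpec(), shape = c(40, 40, 150), seed = 1)
#' sc$movie
#' @export
simulateIQMovie <- function(vessels = list(), clutter = NULL,
                            shape = c(64, 64, 150), pixelPitch = 0.1,
                            f0 = 15e6, c = 1540, prfc = 1e6 / 525,
                            noiseSigma = 3e-4, velocitySpread = 0.01,
                            speckleTau = 0.2, axialPsfSigma = 0.2,
                            seed = 1L) {
  nz <- shape[1]; nx <- shape[2]; nt <- shape[3]
  g <- .gridMm(nz, nx, pixelPitch)
  for (v in vessels) {
    validObject(v)
    if (v@center[1] < 0 || v@center[1] > max(g$z) ||
        v@center[2] < 0 || v@center[2] > max(g$x))
      stop("vessel center outside the field of view")
  }
  .withSeed(seed, {
    blood <- array(0 + 0i, dim = c(nz, nx, nt))
    vtruth <- matrix(0, nz, nx)
    ftruth <- matrix(0, nz, nx)
    bloodMask <- matrix(FALSE, nz, nx)
    aliased <- FALSE
    tIdx <- 0:(nt - 1)
    for (v in vessels) {
      mask <- .vesselMask(v, nz, nx, pixelPitch)
      pix <- which(mask)
      if (!length(pix)) next
      fd <- -2 * f0 * (v@axialVelocity * 1e-3) / c   # modulation freq, Hz
      if (abs(fd) > prfc / 2) aliased <- TRUE
      nsc <- max(1L, round(v@scattererDensity *
                             length(pix) * pixelPitch^2))
      # scatterers drawn uniformly over the vessel cross-section; they
      # advect along z at the (slightly dispersed) vessel velocity, are
      # recycled through the vessel's per-column z extent, and carry the
      # two-way travel phase exp(-i 4 pi f0 z / c) of their instantaneous
      # (unwrapped) depth, so the Doppler shift arises from motion itself
      # and the speckle decorrelates as scatterers cross pixel boundaries,
      # as in real blood.
      pidx <- sample(pix, nsc, replace = TRUE)
      rowp <- (pidx - 1L) %% nz + 1L
      colp <- (pidx - 1L) %/% nz + 1L
      z0 <- (rowp - 1 + stats::runif(nsc, -0.5, 0.5)) * pixelPitch
      x0 <- (colp - 1 + stats::runif(nsc, -0.5, 0.5)) * pixelPitch
      # scatterer amplitudes fluctuate with a Gaussian-shaped spectrum of
      # sd 1/(2 pi speckleTau) Hz, emulating the speckle decorrelation
      # caused by out-of-plane and transverse motion; a Gaussian line has
      # no spectral tails, so slow-flow Doppler tones attenuated by the
      # 70 Hz wall are not buried under their own modulation sidebands.
      # The phase advance below stays exactly at the Doppler rate.
      nAmpComp <- 8L
      ampBw <- 1 / (2 * pi * speckleTau)
      ampP <- matrix(.cnoise(nsc * nAmpComp, sqrt(0.5 / nAmpComp)),
                     nsc, nAmpComp)
      ampF <- matrix(stats::rnorm(nsc * nAmpComp, 0, ampBw), nsc, nAmpComp)
      # laminar shear: each scatterer keeps the profile speed of its own
      # radial position (constant along its axial path), plus a small
      # fractional dispersion
      rsc <- .vesselRadialDist(v, z0, x0)
      vsc <- .profileVelocity(v, rsc) *
        (1 + stats::rnorm(nsc, sd = velocitySpread))
      # per-column z extent of the vessel (mm, pixel-edge bounds)
      colHasMask <- which(colSums(mask) > 0)
      zlo <- rep(NA_real_, nx); zhi <- rep(NA_real_, nx)
      for (cc in colHasMask) {
        rr <- range(which(mask[, cc]))
        zlo[cc] <- (rr[1] - 1.5) * pixelPitch
        zhi[cc] <- (rr[2] - 0.5) * pixelPitch
      }
      L <- pmax(zhi[colp] - zlo[colp], pixelPitch)
      # Each scatterer is rendered with the Gaussian axial envelope of the
      # beamformed point-spread function; a raised-cosine taper over the
      # vessel's axial extent makes the recycling of scatterers through
      # the lumen seamless (no wideband amplitude steps).
      psfHalf <- max(1L, ceiling(3 * axialPsfSigma / pixelPitch))
      offs <- (-psfHalf):psfHalf
      nOff <- length(offs)
      taper <- function(zw, lo, len) {
        u <- (zw - lo) / len
        edge <- 0.15
        w <- rep(1, length(u))
        w[u < edge] <- 0.5 * (1 - cos(pi * u[u < edge] / edge))
        w[u > 1 - edge] <- 0.5 * (1 - cos(pi * (1 - u[u > 1 - edge]) / edge))
        w
      }
      for (tt in seq_len(nt)) {
        zt <- z0 + vsc * (tt - 1) / prfc
        zw <- zlo[colp] + (zt - zlo[colp]) %% L
        At <- as.vector((ampP * exp(2i * pi * ampF * ((tt - 1) / prfc))) %*%
                          rep(1, nAmpComp))
        contrib <- At * exp(-4i * pi * f0 * (zt * 1e-3) / c) *
          taper(zw, zlo[colp], L)
        zpix <- zw / pixelPitch + 1          # fractional row index
        rowC <- round(zpix)
        rows <- rep(rowC, nOff) + rep(offs, each = nsc)
        wts <- exp(-((rep(zpix, nOff) - rows)^2) *
                     (pixelPitch^2 / (2 * axialPsfSigma^2)))
        ok <- rows >= 1L & rows <= nz
        idx <- rows[ok] + (rep(colp, nOff)[ok] - 1L) * nz
        cw <- rep(contrib, nOff)[ok] * wts[ok]
        dep <- rowsum(cbind(Re(cw), Im(cw)), idx)
        at <- as.integer(rownames(dep))
        plane <- blood[, , tt]
        plane[at] <- plane[at] + complex(real = dep[, 1],
                                         imaginary = dep[, 2])
        blood[, , tt] <- plane
      }
      zPix <- outer(g$z, rep(1, nx))
      xPix <- outer(rep(1, nz), g$x)
      vPix <- .profileVelocity(v, .vesselRadialDist(v, zPix, xPix))
      vtruth[mask] <- vPix[mask]
      ftruth[mask] <- -2 * f0 * (vPix[mask] * 1e-3) / c
      bloodMask <- bloodMask | mask
    }
    bloodRms <- if (any(bloodMask))
      sqrt(mean(Mod(blood[rep(bloodMask, nt)])^2)) else 1
    clutterMovie <- array(0 + 0i, dim = c(nz, nx, nt))
    if (!is.null(clutter)) {
      validObject(clutter)
      # mode energies decay geometrically, emulating the decaying singular
      # spectrum of real tissue motion while keeping the process exactly
      # rank-nModes
      for (j in seq_len(clutter@nModes)) {
        sf <- .smoothField(nz, nx)
        env <- .bandlimitedEnvelope(nt, prfc, clutter@modeBandwidth)
        clutterMovie <- clutterMovie + sqrt(clutter@modeDecay^(j - 1)) *
          array(outer(as.vector(sf), env), dim = c(nz, nx, nt))
      }
      cRms <- sqrt(mean(Mod(clutterMovie)^2))
      clutterMovie <- clutterMovie *
        (clutter@amplitudeRatio * bloodRms / cRms)
    }
    noise <- if (noiseSigma > 0)
      array(.cnoise(nz * nx * nt, noiseSigma * bloodRms),
            dim = c(nz, nx, nt)) else 0
    data <- blood + clutterMovie + noise
    movie <- IQMovie(data, pixelPitch = pixelPitch, f0 = f0, c = c,
                     prfc = prfc)
    if (aliased)
      warning("scene contains Doppler frequencies beyond +/- prfc/2 (aliased)")
    list(movie = movie,
         truth = list(velocity = vtruth, dopplerHz = ftruth,
                      bloodMask = bloodMask, bloodRms = bloodRms,
                      bloodMovie = blood, clutterMovie = clutterMovie,
                      aliased = aliased))
  })
}
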