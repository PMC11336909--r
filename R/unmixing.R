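## Multispectral photoacoustic unmixing: per-wavelength set averaging,
## pulse-energy-normalized system matrix, per-pixel non-negative least
## squares, and the derived oxygen-saturation and ICG products.

# Molar extinction coefficients (cm^-1 / M) at the supported wavelengths,
# frozen from the standard compiled optical-absorption tables so that
# simulation and unmixing share one versioned constant set. Hemoglobin
# values are for 150 g/L whole blood conventions; ICG is the aqueous/plasma
# near-infrared dye spectrum peaking near 800 nm.
.EXTINCTION <- data.frame(
  wavelength = c(750, 800, 850),
  HbO = c(518.0, 816.0, 1058.0),
  HbD = c(1405.24, 761.84, 691.32),
  ICG = c(1.30e5, 2.54e5, 0.50e5)
)

#' Molar extinction coefficients of the supported chromophores
#'
#' Frozen constants for oxy-hemoglobin, deoxy-hemoglobin and indocyanine
#' green at the supported wavelengths; the same table drives the simulator
#' and the unmixing, making recovery tests exact.
#'
#' @param wavelengths nm; every requested wavelength must be tabulated.
#' @return numeric matrix (wavelength x chromophore), columns HbO, HbD, ICG.
#' @examples
#' extinctionCoefficients(c(750, 800, 850))
#' @export
extinctionCoefficients <- function(wavelengths = c(750, 800, 850)) {
  idx <- match(wavelengths, .EXTINCTION$wavelength)
  if (anyNA(idx))
    stop("no extinction data for wavelength(s) ",
         paste(wavelengths[is.na(idx)], collapse = ", "), " nm")
  m <- as.matrix(.EXTINCTION[idx, c("HbO", "HbD", "ICG")])
  rownames(m) <- as.character(wavelengths)
  m
}

#' Assemble a PA stack from a linear block of frames
#'
#' Interprets a (depth x lateral x frame) block acquired while cycling
#' through the wavelength list — e.g. the 16-frame block of 5 sets of
#' 3 wavelengths plus one spare — keeping only the complete wavelength
#' sets and discarding trailing spare frames.
#'
#' @param frames numeric array (depth x lateral x frame), frames in firing
#'   order.
#' @param wavelengths nm, in firing order.
#' @param pulseEnergies mJ per wavelength.
#' @param pixelPitch mm per pixel.
#' @return A \code{\link{PAStack}} of the complete sets.
#' @export
paStackFromFrames <- function(frames, wavelengths = c(750, 800, 850),
                              pulseEnergies = rep(1, length(wavelengths)),
                              pixelPitch = 0.1) {
  d <- dim(frames)
  nwl <- length(wavelengths)
  nSets <- d[3] %/% nwl
  if (nSets < 1L) stop("block holds zero complete wavelength sets")
  arr <- array(0, dim = c(d[1], d[2], nwl, nSets))
  for (s in seq_len(nSets)) for (w in seq_len(nwl))
    arr[, , w, s] <- frames[, , (s - 1L) * nwl + w]
  PAStack(arr, wavelengths, pulseEnergies, pixelPitch)
}

#' Average the repeated wavelength sets of a PA stack
#'
#' Repeated sets at each wavelength are averaged to improve SNR (noise sd
#' drops by 1/sqrt(nSets)); incomplete spare frames are assumed already
#' dropped by the block reader, so every stored set is complete.
#'
#' @param stack a \code{\link{PAStack}}.
#' @return A \code{PAStack} with a single averaged set per wavelength.
#' @export
averageWavelengthSets <- function(stack) {
  d <- dim(stack@images)
  if (d[4] < 1L) stop("stack contains zero complete wavelength sets")
  avg <- array(0, dim = c(d[1], d[2], d[3], 1L))
  for (w in seq_len(d[3]))
    avg[, , w, 1L] <- apply(stack@images[, , w, , drop = FALSE], c(1, 2),
                            mean)
  PAStack(avg, stack@wavelengths, stack@pulseEnergies,
          pixelPitch = stack@pixelPitch)
}

#' Build the energy-normalized unmixing system matrix
#'
#' Row lambda of the system matrix is the extinction spectrum at that
#' wavelength scaled by its measured pulse energy, since photoacoustic
#' amplitude is proportional to the delivered energy. Scaling is by the
#' absolute per-wavelength energy, which makes the unmixed concentrations
#' invariant under a joint rescaling of all energies and images.
#'
#' @param wavelengths nm.
#' @param pulseEnergies mJ per wavelength, positive.
#' @param table extinction matrix from
#'   \code{\link{extinctionCoefficients}} (looked up by default).
#' @return numeric matrix (wavelength x chromophore).
#' @export
buildSystemMatrix <- function(wavelengths = c(750, 800, 850),
                              pulseEnergies = rep(1, length(wavelengths)),
                              table = extinctionCoefficients(wavelengths)) {
  if (any(pulseEnergies <= 0)) stop("pulseEnergies must be positive")
  if (!all(c("HbO", "HbD", "ICG") %in% colnames(table)))
    stop("extinction table must provide columns HbO, HbD, ICG")
  if (nrow(table) != length(wavelengths))
    stop("one table row per wavelength required")
  table * pulseEnergies
}

#' Per-pixel non-negative least-squares unmixing
#'
#' Solves c = argmin ||E c - p||_2 subject to c >= 0 at every pixel
#' (Lawson-Hanson active set via \code{pracma::lsqnonneg}); pixels whose
#' unconstrained solution is already non-negative take it directly, which
#' is the same optimum.
#'
#' @param averaged a \code{\link{PAStack}} with one set (see
#'   \code{\link{averageWavelengthSets}}), or a 3-D array
#'   (depth x lateral x wavelength).
#' @param E system matrix from \code{\link{buildSystemMatrix}}.
#' @return A \code{\link{ConcentrationMaps}} with the per-pixel residual
#'   norm of the fit.
#' @export
unmixStack <- function(averaged, E) {
  imgs <- if (is(averaged, "PAStack")) {
    if (dim(averaged@images)[4] != 1L)
      averaged <- averageWavelengthSets(averaged)
    averaged@images[, , , 1L]
  } else averaged
  d <- dim(imgs)
  if (length(d) != 3L) stop("averaged frames must be 3-D")
  if (d[3] < ncol(E))
    stop("need at least as many wavelengths as chromophores")
  if (d[3] != nrow(E)) stop("one system-matrix row per wavelength required")
  P <- matrix(imgs, nrow = d[1] * d[2], ncol = d[3])     # pixels x lambda
  # unconstrained fast path
  EtE <- crossprod(E)
  Cun <- t(solve(EtE, t(P %*% E)))                       # pixels x chromo
  neg <- which(apply(Cun < -1e-12, 1, any))
  for (i in neg)
    Cun[i, ] <- pracma::lsqnonneg(E, P[i, ])$x
  Cun[Cun < 0] <- 0
  res <- sqrt(rowSums((P - Cun %*% t(E))^2))
  new("ConcentrationMaps",
      hbo = matrix(Cun[, 1L], d[1], d[2]),
      hbd = matrix(Cun[, 2L], d[1], d[2]),
      icg = matrix(Cun[, 3L], d[1], d[2]),
      residual = matrix(res, d[1], d[2]))
}

#' Oxygen-saturation map from unmixed hemoglobin
#'
#' SO2 = HbO / (HbO + HbD), computed only where total hemoglobin exceeds
#' the support floor (default 1% of the map's maximum HbO + HbD); pixels
#' below the floor are NA and excluded from ROI statistics.
#'
#' @param maps a \code{\link{ConcentrationMaps}}.
#' @param floor absolute support floor; NULL for the 1%-of-max default.
#' @return An \code{\link{SO2Map}}.
#' @export
computeSo2 <- function(maps, floor = NULL) {
  tot <- maps@hbo + maps@hbd
  if (is.null(floor)) floor <- 0.01 * max(tot)
  support <- tot > floor
  s <- matrix(NA_real_, nrow(tot), ncol(tot))
  s[support] <- maps@hbo[support] / tot[support]
  new("SO2Map", so2 = s, supportMask = support)
}

#' ICG time-activity series over an ROI
#'
#' Per-frame mean unmixed ICG over the ROI, with a centered moving-average
#' smoothed overlay (window 1 returns the raw series).
#'
#' @param mapsList list of \code{\link{ConcentrationMaps}}, one per frame.
#' @param roiMask logical matrix.
#' @param smoothWindow odd moving-average window length in frames.
#' @param framePeriod seconds per frame.
#' @return list: \code{raw} and \code{smoothed} \code{\link{TimeSeries}}.
#' @export
icgTimeActivity <- function(mapsList, roiMask, smoothWindow = 3L,
                            framePeriod = 1.9) {
  if (length(mapsList) < 2L) stop("need at least 2 time points")
  if (!any(roiMask)) stop("ROI mask is empty")
  raw <- vapply(mapsList, function(m) mean(m@icg[roiMask]), numeric(1))
  w <- as.integer(smoothWindow)
  sm <- if (w <= 1L) raw else {
    half <- (w - 1L) %/% 2L
    n <- length(raw)
    vapply(seq_len(n), function(i)
      mean(raw[max(1L, i - half):min(n, i + half)]), numeric(1))
  }
  list(raw = timeSeries(raw, framePeriod = framePeriod),
       smoothed = timeSeries(sm, framePeriod = framePeriod))
}

#' Log-compressed ICG display map
#'
#' 20 log10 compression relative to the map maximum, floored.
#'
#' @param maps a \code{\link{ConcentrationMaps}}.
#' @param floorDb dB floor.
#' @return numeric matrix in dB (max = 0 dB).
#' @export
icgDb <- function(maps, floorDb = -40) {
  m <- max(maps@icg)
  if (m <= 0) return(matrix(floorDb, nrow(maps@icg), ncol(maps@icg)))
  20 * log10(pmax(maps@icg / m, 10^(floorDb / 20)))
}

#' Full unmixing chain for a PA stack
#'
#' Set averaging, energy-normalized system matrix, NNLS unmixing, and the
#' derived oxygen-saturation map.
#'
#' @param stack a \code{\link{PAStack}}.
#' @param so2Floor support floor passed to \code{\link{computeSo2}}.
#' @return list: \code{concentrations}, \code{so2}.
#' @export
unmixPAStack <- function(stack, so2Floor = NULL) {
  avg <- averageWavelengthSets(stack)
  E <- buildSystemMatrix(stack@wavelengths, stack@pulseEnergies)
  conc <- unmixStack(avg, E)
  list(concentrations = conc, so2 = computeSo2(conc, so2Floor))
}
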