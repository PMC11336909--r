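## Directional autocorrelation velocimetry. After SVD clutter rejection and
## the 70 Hz slow-time high-pass, the per-pixel slow-time spectrum is split
## at 0 Hz into positive- and negative-frequency components; each component
## is kept only where it carries enough of the total spectral power (> 0.2
## positive, > 0.25 negative) and its normalized lag-1 autocorrelation
## exceeds 0.2. The lag-1 (Kasai-type) autocorrelation phase then gives the
## axial Doppler frequency and hence the signed axial velocity
##   v_z = c * f_d / (2 f0),  f_d = prfc * arg(R(1)) / (2 pi).
## Sign convention: descending flow (away from the transducer, deeper)
## produces a negative Doppler shift and is displayed red; ascending blue.

#' Directional filtering of an IQ movie
#'
#' Splits each pixel's slow-time spectrum at 0 Hz and reconstructs the
#' positive- and negative-frequency components by inverse FFT. The DC bin is
#' excluded from both components (the clutter-filtered input is DC-free);
#' for even-length series the Nyquist bin is assigned to the negative
#' component. Power fractions are relative to total spectral power, so
#' posFraction + negFraction <= 1 with equality when the DC bin is empty.
#'
#' @param movie an \code{\link{IQMovie}} (clutter-filtered and high-passed).
#' @return list: \code{pos}, \code{neg} (component \code{IQMovie}s),
#'   \code{posFraction}, \code{negFraction} (per-pixel power fractions).
#' @examples
#' tone <- exp(2i * pi * 5 * (0:63) / 64)
#' m <- IQMovie(array(tone, dim = c(1, 1, 64)))
#' directionalSplit(m)$posFraction  # 1
#' @export
directionalSplit <- function(movie) {
  d <- dim(movie@data)
  nt <- d[3]
  if (nt < 2L) stop("directional split needs at least 2 frames")
  X <- t(.casorati(movie@data))           # time x space
  S <- stats::mvfft(X)
  # bins: 1 = DC; strictly positive frequencies next; the rest (including
  # the Nyquist bin for even nt) form the negative component
  kPos <- if (nt >= 3L) 2:floor((nt + 1) / 2) else integer(0)
  kAll <- seq_len(nt)
  kNeg <- setdiff(kAll, c(1L, kPos))
  powTot <- colSums(Mod(S)^2)
  powPos <- colSums(Mod(S[kPos, , drop = FALSE])^2)
  powNeg <- colSums(Mod(S[kNeg, , drop = FALSE])^2)
  safeTot <- ifelse(powTot > 0, powTot, 1)
  mkMovie <- function(keep) {
    Sk <- S
    Sk[setdiff(kAll, keep), ] <- 0
    comp <- stats::mvfft(Sk, inverse = TRUE) / nt
    out <- movie
    out@data <- .uncasorati(t(comp), d)
    out
  }
  list(pos = mkMovie(kPos), neg = mkMovie(kNeg),
       posFraction = matrix(powPos / safeTot, d[1], d[2]),
       negFraction = matrix(powNeg / safeTot, d[1], d[2]))
}

#' Lag-1 autocorrelation axial velocity estimate
#'
#' For each pixel, R(1) = sum_t conj(IQ(t)) IQ(t+1); the Doppler frequency
#' is prfc * arg(R(1)) / (2 pi) and the signed axial velocity
#' v = c f_d / (2 f0), bounded by the Nyquist velocity c prfc / (4 f0) by
#' construction of arg() in (-pi, pi]. The normalized magnitude
#' |R(1)| / R(0) is returned for validity masking; pixels with R(0) = 0 are
#' undefined (NA velocity, 0 autocorrelation).
#'
#' @param movie an \code{\link{IQMovie}}, typically one directional
#'   component from \code{\link{directionalSplit}}.
#' @return list: \code{velocity} (mm/s, signed: positive for
#'   positive-frequency motion, i.e. ascending under the package's
#'   convention), \code{autocorr} (normalized |R(1)|/R(0)), \code{dopplerHz}.
#' @examples
#' tone <- exp(2i * pi * 200 * (0:149) / 1904.76)
#' m <- IQMovie(array(tone, dim = c(1, 1, 150)), prfc = 1904.76)
#' axialVelocity(m)$velocity  # ~ +10.27 mm/s (positive Doppler)
#' @export
axialVelocity <- function(movie) {
  d <- dim(movie@data)
  nt <- d[3]
  if (nt < 2L) stop("autocorrelation needs at least 2 frames")
  X <- .casorati(movie@data)              # space x time
  R1 <- rowSums(Conj(X[, -nt, drop = FALSE]) * X[, -1L, drop = FALSE])
  R0 <- rowSums(Mod(X)^2)
  fd <- movie@prfc * Arg(R1) / (2 * pi)
  v <- movie@c * fd / (2 * movie@f0) * 1e3   # mm/s
  ac <- ifelse(R0 > 0, Mod(R1) / R0, 0)
  v[R0 == 0] <- NA_real_
  list(velocity = matrix(v, d[1], d[2]),
       autocorr = matrix(ac, d[1], d[2]),
       dopplerHz = matrix(fd, d[1], d[2]))
}

#' Validity masks for the directional components
#'
#' A positive component is valid where its power fraction exceeds the 0.2
#' floor and its normalized lag-1 autocorrelation exceeds 0.2; the negative
#' component analogously with the 0.25 power floor.
#'
#' @param posFraction,negFraction per-pixel power fractions from
#'   \code{\link{directionalSplit}}.
#' @param posAutocorr,negAutocorr normalized lag-1 autocorrelation of the
#'   respective component from \code{\link{axialVelocity}}.
#' @param config a \code{\link{velocimetryConfig}}.
#' @return list: \code{validPos}, \code{validNeg} logical matrices.
#' @export
validityMasks <- function(posFraction, negFraction, posAutocorr,
                          negAutocorr, config = velocimetryConfig()) {
  validObject(config)
  list(validPos = posFraction > config@posPowerFractionMin &
         posAutocorr > config@autocorrMin,
       validNeg = negFraction > config@negPowerFractionMin &
         negAutocorr > config@autocorrMin)
}

#' Assemble the signed blood-flow map from directional estimates
#'
#' Descending velocities come from the negative-frequency component (flow
#' away from the transducer), ascending from the positive-frequency
#' component; each is populated only where its validity mask holds. Pixels
#' valid in both directions keep both per-direction maps (overlay); the
#' signed map takes the larger-magnitude component, positive = descending.
#'
#' @param velPos,velNeg signed velocity matrices of the positive and
#'   negative components from \code{\link{axialVelocity}}.
#' @param validPos,validNeg logical masks from \code{\link{validityMasks}}.
#' @return A \code{\link{VelocityMap}}.
#' @export
assembleCbfMap <- function(velPos, velNeg, validPos, validNeg) {
  stopifnot(identical(dim(velPos), dim(velNeg)),
            identical(dim(velPos), dim(validPos)),
            identical(dim(velPos), dim(validNeg)))
  vAsc <- matrix(0, nrow(velPos), ncol(velPos))
  vDesc <- vAsc
  vAsc[validPos] <- abs(velPos[validPos])      # positive Doppler: ascending
  vDesc[validNeg] <- abs(velNeg[validNeg])     # negative Doppler: descending
  vAsc[is.na(vAsc)] <- 0
  vDesc[is.na(vDesc)] <- 0
  vSigned <- ifelse(vDesc >= vAsc, vDesc, -vAsc)
  vSigned[!validPos & !validNeg] <- 0
  new("VelocityMap", vDescending = vDesc, vAscending = vAsc,
      validPos = validPos, validNeg = validNeg, vSigned = vSigned)
}

#' Full velocimetry chain: SVD, high-pass, split, autocorrelation
#'
#' Runs the blood-flow path in the fixed stage order: SVD clutter rejection
#' (10 components), 70 Hz 4th-order zero-phase Butterworth high-pass,
#' directional split, per-component lag-1 autocorrelation velocity, validity
#' masking, and assembly of the signed map.
#'
#' @param movie a raw \code{\link{IQMovie}}.
#' @param config a \code{\link{velocimetryConfig}}.
#' @return A \code{\link{VelocityMap}}.
#' @examples
#' sc <- simulateIQMovie(list(vesselSpec(c(2, 2), 0.3, 10)), clutterSpec(),
#'                       shape = c(40, 40, 150), seed = 3)
#' vm <- cbfMap(sc$movie)
#' mean(vDescending(vm)[sc$truth$bloodMask])
#' @export
cbfMap <- function(movie, config = velocimetryConfig()) {
  validObject(config)
  filtered <- svdClutterFilter(movie, config@svdNReject)$movie
  filtered <- slowTimeHighpass(filtered, config@highpassCutoff, 4L)
  split <- directionalSplit(filtered)
  estPos <- axialVelocity(split$pos)
  estNeg <- axialVelocity(split$neg)
  masks <- validityMasks(split$posFraction, split$negFraction,
                         estPos$autocorr, estNeg$autocorr, config)
  assembleCbfMap(estPos$velocity, estNeg$velocity,
                 masks$validPos, masks$validNeg)
}

#' Nyquist velocity of an acquisition
#'
#' @param movie an \code{\link{IQMovie}}.
#' @return The unaliased axial speed bound c * prfc / (4 f0), mm/s.
#' @export
nyquistVelocity <- function(movie) {
  movie@c * movie@prfc / (4 * movie@f0) * 1e3
}
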