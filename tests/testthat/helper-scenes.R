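# Shared scene builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# Single descending vessel under the standard acquisition (15 MHz,
# compounded PRF 1904.76 Hz, 0.1 mm pitch), tissue clutter 30 dB above
# blood. Used by the velocimetry recovery tests.
velocityScene <- function(v, seed, nt = 400L, shape = c(32L, 32L)) {
  simulateIQMovie(
    list(vesselSpec(c(1.6, 1.6), 0.7, v)),
    clutterSpec(),
    shape = c(shape, nt), pixelPitch = 0.1, f0 = 15e6, c = 1540,
    prfc = 1e6 / 525, seed = seed)
}

# Rich multi-vessel cortex-like scene: six parabolic vessels of mixed
# speed and direction, broadband speckle. Used where blood must occupy
# many singular components (SVD power-preservation property).
richScene <- function(seed, nt = 400L) {
  vessels <- list(
    vesselSpec(c(1.2, 0.8), 0.5, 8, profile = "parabolic"),
    vesselSpec(c(1.2, 2.2), 0.5, -14, profile = "parabolic"),
    vesselSpec(c(1.2, 3.6), 0.5, 22, profile = "parabolic"),
    vesselSpec(c(3.4, 1.0), 0.5, -28, profile = "parabolic"),
    vesselSpec(c(3.4, 2.4), 0.5, 36, profile = "parabolic"),
    vesselSpec(c(3.4, 3.8), 0.5, -40, profile = "parabolic"))
  simulateIQMovie(vessels, clutterSpec(nModes = 3L),
                  shape = c(48L, 48L, nt), speckleTau = 0.003,
                  velocitySpread = 0.12, axialPsfSigma = 0.1, seed = seed)
}

# Mean |IQ|^2 over masked pixels of a movie array.
maskedPower <- function(arr, mask) {
  d <- dim(arr)
  mean(Mod(matrix(arr, d[1] * d[2], d[3])[as.vector(mask), ])^2)
}

# Random non-negative chromophore phantom with noise at the given SNR (dB,
# relative to the mean absolute clean amplitude across wavelengths).
randomPhantom <- function(nz = 20L, nx = 20L, snrDb = 30) {
  hboT <- matrix(stats::runif(nz * nx, 0.2, 1), nz)
  hbdT <- matrix(stats::runif(nz * nx, 0.2, 1), nz)
  icgT <- matrix(stats::runif(nz * nx, 0, 0.005), nz)
  E <- buildSystemMatrix()
  sig <- mean(abs(cbind(as.vector(hboT), as.vector(hbdT),
                        as.vector(icgT)) %*% t(E)))
  list(phantom = chromophorePhantom(hboT, hbdT, icgT,
                                    noiseSigma = sig * 10^(-snrDb / 20)),
       hbo = hboT, hbd = hbdT, icg = icgT)
}

# Brute-force minimum-cost assignment over all row permutations.
bruteForceAssign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestCost) { bestCost <- cc; best <- p }
  }
  list(assignment = best, cost = bestCost)
}
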