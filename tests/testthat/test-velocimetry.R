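prf <- 1e6 / 525

toneMovie <- function(freq, nt = 150, npx = c(1, 1)) {
  tone <- exp(2i * pi * freq * (0:(nt - 1)) / prf)
  IQMovie(array(rep(tone, each = prod(npx)), dim = c(npx, nt)), prfc = prf)
}

test_that("directional split separates one-sided spectra exactly", {
  # bin-aligned tone (16 cycles over 150 frames) for an exact one-sided
  # spectrum; leakage-free by construction
  ds <- directionalSplit(toneMovie(16 * prf / 150))
  expect_equal(ds$posFraction[1, 1], 1, tolerance = 1e-10)
  expect_equal(ds$negFraction[1, 1], 0, tolerance = 1e-10)
  # real cosine: Hermitian spectrum splits 0.5 / 0.5 (no DC, even length)
  k <- 10; nt <- 150
  cosv <- cos(2 * pi * k * (0:(nt - 1)) / nt) + 0i
  dc <- directionalSplit(IQMovie(array(cosv, dim = c(1, 1, nt)),
                                 prfc = prf))
  expect_equal(dc$posFraction[1, 1], 0.5, tolerance = 1e-10)
  expect_equal(dc$negFraction[1, 1], 0.5, tolerance = 1e-10)
  # sum of equal-power opposite phasors: each component recovered < 1%
  up <- exp(2i * pi * (24 * prf / 150) * (0:149) / prf)
  dn <- exp(-2i * pi * (36 * prf / 150) * (0:149) / prf + 0.7i)
  mix <- IQMovie(array(up + dn, dim = c(1, 1, 150)), prfc = prf)
  dm <- directionalSplit(mix)
  expect_lt(mean(Mod(iqData(dm$pos)[1, 1, ] - up)), 0.01)
  expect_lt(mean(Mod(iqData(dm$neg)[1, 1, ] - dn)), 0.01)
  expect_error(directionalSplit(IQMovie(array(1 + 0i, c(1, 1, 1)))),
               "2 frames")
})

test_that("power fractions sum to at most one, with equality when DC-free", {
  set.seed(8)
  m <- IQMovie(array(complex(real = rnorm(4 * 4 * 64),
                             imaginary = rnorm(4 * 4 * 64)),
                     dim = c(4, 4, 64)), prfc = prf)
  ds <- directionalSplit(m)
  expect_true(all(ds$posFraction + ds$negFraction <= 1 + 1e-12))
  # remove DC per pixel: fractions must sum to 1
  arr <- iqData(m)
  for (i in 1:4) for (j in 1:4)
    arr[i, j, ] <- arr[i, j, ] - mean(arr[i, j, ])
  ds0 <- directionalSplit(IQMovie(arr, prfc = prf))
  expect_equal(unname(ds0$posFraction + ds0$negFraction),
               matrix(1, 4, 4), tolerance = 1e-10)
})

test_that("validity rules apply the 0.2 / 0.25 power floors and the autocorrelation floor", {
  frac <- function(p, n, ap = 0.9, an = 0.9)
    validityMasks(matrix(p), matrix(n), matrix(ap), matrix(an))
  # positive fraction at 0.19: invalid regardless of autocorrelation
  expect_false(frac(0.19, 0.5)$validPos[1, 1])
  expect_true(frac(1.0, 0.0)$validPos[1, 1])
  # negative floor is stricter: 0.24 fails, 0.26 passes
  expect_false(frac(0.5, 0.24)$validNeg[1, 1])
  expect_true(frac(0.5, 0.26)$validNeg[1, 1])
  # autocorrelation floor 0.2 applies to both
  expect_false(validityMasks(matrix(0.9), matrix(0.9), matrix(0.15),
                             matrix(0.9))$validPos[1, 1])
})

test_that("lag-1 autocorrelation recovers tone velocities and wraps at Nyquist", {
  # constant-phase series: zero velocity
  est0 <- axialVelocity(IQMovie(array(1 + 1i, dim = c(2, 2, 30)),
                                prfc = prf))
  expect_equal(unname(est0$velocity), matrix(0, 2, 2))
  # 200 Hz tone: v = c f / (2 f0) = 10.27 mm/s; cross-checked against a
  # brute-force linear phase fit on the same series
  m <- toneMovie(200)
  est <- axialVelocity(m)
  expect_equal(est$velocity[1, 1], 1540 * 200 / (2 * 15e6) * 1e3,
               tolerance = 1e-6)
  phase <- signal::unwrap(Arg(iqData(m)[1, 1, ]))
  slope <- coef(lm(phase ~ I(0:149)))[2]
  vFit <- 1540 * (slope * prf / (2 * pi)) / (2 * 15e6) * 1e3
  expect_equal(est$velocity[1, 1], unname(vFit), tolerance = 1e-6)
  # for a pure tone |R(1)| sums N-1 unit terms against R(0)'s N
  expect_equal(est$autocorr[1, 1], 149 / 150, tolerance = 1e-10)
  # beyond Nyquist the phase wraps: prf/2 + 10 aliases to -(prf/2 - 10)
  estA <- axialVelocity(toneMovie(prf / 2 + 10))
  expect_equal(estA$dopplerHz[1, 1], -(prf / 2 - 10), tolerance = 1e-6)
  # all-zero pixel is undefined
  estZ <- axialVelocity(IQMovie(array(0 + 0i, dim = c(1, 1, 10)),
                                prfc = prf))
  expect_true(is.na(estZ$velocity[1, 1]))
  expect_identical(estZ$autocorr[1, 1], 0)
})

test_that("velocities never exceed the Nyquist bound", {
  set.seed(3)
  m <- IQMovie(array(complex(real = rnorm(800), imaginary = rnorm(800)),
                     dim = c(4, 4, 50)), prfc = prf)
  est <- axialVelocity(m)
  expect_true(all(abs(est$velocity) <= nyquistVelocity(m) + 1e-9))
})

test_that("map assembly respects masks and the descending sign convention", {
  z <- matrix(0, 2, 2)
  allFalse <- matrix(FALSE, 2, 2)
  vm <- assembleCbfMap(z + 5, z - 7, allFalse, allFalse)
  expect_true(all(vSigned(vm) == 0))
  vP <- matrix(c(3, 0, 0, 0), 2); vN <- matrix(c(0, -8, 0, 0), 2)
  mP <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  mN <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2)
  vm2 <- assembleCbfMap(vP, vN, mP, mN)
  expect_identical(vAscending(vm2)[1, 1], 3)
  expect_identical(vDescending(vm2)[2, 1], 8)
  expect_identical(vSigned(vm2)[1, 1], -3)  # ascending negative
  expect_identical(vSigned(vm2)[2, 1], 8)   # descending positive
})

test_that("the full chain recovers a descending tube and mirrors on sign flip", {
  sc <- velocityScene(10, seed = 21)
  vm <- cbfMap(sc$movie)
  mask <- sc$truth$bloodMask
  expect_equal(mean(vDescending(vm)[mask]), 10, tolerance = 0.05)
  expect_lt(mean(vAscending(vm)[mask]), 0.5)
  # mirrored ascending tube: roles swap
  scA <- velocityScene(-10, seed = 21)
  vmA <- cbfMap(scA$movie)
  expect_equal(mean(vAscending(vmA)[mask]), 10, tolerance = 0.05)
  expect_lt(mean(vDescending(vmA)[mask]), 0.5)
})
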