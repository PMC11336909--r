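test_that("zero rejection is the identity and rank-1 clutter is annihilated", {
  sc <- simulateIQMovie(list(vesselSpec(c(1.5, 1.5), 0.4, 10)),
                        clutterSpec(), shape = c(16, 16, 40), seed = 5)
  out0 <- svdClutterFilter(sc$movie, 0)
  expect_equal(iqData(out0$movie), iqData(sc$movie), tolerance = 1e-12)
  # rank-1 static movie: one component removes everything
  static <- IQMovie(array(outer(complex(real = rnorm(64),
                                        imaginary = rnorm(64)),
                                rep(1 + 0i, 20)), dim = c(8, 8, 20)))
  outS <- svdClutterFilter(static, 1)
  expect_lt(sum(Mod(iqData(outS$movie))^2),
            1e-10 * sum(Mod(iqData(static))^2))
})

test_that("filtered energy equals the sum of retained squared singular values", {
  sc <- simulateIQMovie(list(vesselSpec(c(1.5, 1.5), 0.4, 15)),
                        clutterSpec(), shape = c(16, 16, 50), seed = 6)
  out <- svdClutterFilter(sc$movie, 9)
  resid <- sum(Mod(iqData(out$movie))^2)
  expect_equal(resid, sum(out$singularValues[-(1:9)]^2),
               tolerance = 1e-8)
  # independent oracle: singular values from the eigendecomposition of the
  # time-by-time covariance of the Casorati matrix
  X <- matrix(iqData(sc$movie), 256, 50)
  ev <- sort(Re(eigen(Conj(t(X)) %*% X, symmetric = TRUE,
                      only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(out$singularValues^2, pmax(ev, 0), tolerance = 1e-8)
  expect_true(all(diff(out$singularValues) <= 1e-8))
})

test_that("removing every component is refused", {
  m <- IQMovie(array(complex(real = rnorm(80), imaginary = rnorm(80)),
                     dim = c(4, 4, 5)))
  expect_error(svdClutterFilter(m, 5), "all signal")
  expect_error(svdClutterFilter(IQMovie(array(1 + 0i, dim = c(4, 4, 1))),
                                1), "2 frames")
})

test_that("SVD filtering is linear", {
  mk <- function(seed) simulateIQMovie(list(), clutterSpec(nModes = 2L),
                                       shape = c(10, 10, 30),
                                       seed = seed)$movie
  x <- mk(1); y <- mk(2)
  # same subspace is removed when filtering the scaled sum of one movie
  f <- function(m, a) {
    mm <- m; mm@data <- a * m@data
    iqData(svdClutterFilter(mm, 2)$movie)
  }
  expect_equal(f(x, 3), 3 * f(x, 1), tolerance = 1e-10)
})

test_that("slow-time high-pass rejects DC and attenuates the cutoff to ~0.25 power", {
  m <- IQMovie(array(2 + 1i, dim = c(3, 3, 150)))
  out <- slowTimeHighpass(m)
  expect_lt(max(Mod(iqData(out))), 1e-6 * Mod(2 + 1i))
  # complex tone at prf/4 (far above cutoff): amplitude preserved within 1%
  prf <- 1e6 / 525
  tone <- exp(2i * pi * (prf / 4) * (0:599) / prf)
  mt <- IQMovie(array(rep(tone, each = 4), dim = c(2, 2, 600)))
  ot <- slowTimeHighpass(mt)
  expect_equal(mean(Mod(iqData(ot))), 1, tolerance = 0.01)
  # tone exactly at the cutoff: two -3 dB passes leave ~0.25 of the power
  tc <- exp(2i * pi * 70 * (0:599) / prf)
  mc <- IQMovie(array(rep(tc, each = 4), dim = c(2, 2, 600)))
  oc <- slowTimeHighpass(mc)
  expect_equal(mean(Mod(iqData(oc))^2), 0.25, tolerance = 0.02)
  expect_error(slowTimeHighpass(IQMovie(array(1 + 0i, dim = c(2, 2, 10)))),
               "too short")
  expect_error(slowTimeHighpass(m, cutoff = 1000), "twice the cutoff")
})

test_that("rank rejection preserves blood power on a rich scene", {
  sc <- richScene(seed = 1)
  out <- svdClutterFilter(sc$movie, 9)
  ratio <- maskedPower(iqData(out$movie), sc$truth$bloodMask) /
    maskedPower(sc$truth$bloodMovie, sc$truth$bloodMask)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})
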