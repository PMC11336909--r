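test_that("wavelength-set averaging reduces noise as 1/sqrt(n)", {
  # identical sets: average equals any single set
  img <- array(runif(6 * 6 * 3), dim = c(6, 6, 3, 1))
  st <- PAStack(array(rep(img, 5), dim = c(6, 6, 3, 5)),
                c(750, 800, 850), c(1, 1, 1))
  avg <- averageWavelengthSets(st)
  expect_equal(avg@images[, , , 1], img[, , , 1], tolerance = 1e-12)
  # Monte-Carlo: residual noise sd of the 5-set mean is sigma / sqrt(5)
  set.seed(12)
  sds <- replicate(40, {
    noisy <- array(rnorm(8 * 8 * 3 * 5, sd = 1), dim = c(8, 8, 3, 5))
    sd(averageWavelengthSets(PAStack(noisy, c(750, 800, 850),
                                     c(1, 1, 1)))@images)
  })
  expect_equal(mean(sds), 1 / sqrt(5), tolerance = 0.1)
})

test_that("a 16-frame block yields exactly 5 sets with the spare discarded", {
  frames <- array(rnorm(4 * 4 * 16), dim = c(4, 4, 16))
  st <- paStackFromFrames(frames)
  expect_equal(dim(st@images), c(4, 4, 3, 5))
  # frame 16 (the spare) is not used anywhere
  expect_equal(st@images[, , 1, 5], frames[, , 13], tolerance = 1e-15)
  expect_equal(st@images[, , 3, 5], frames[, , 15], tolerance = 1e-15)
  expect_error(paStackFromFrames(array(0, dim = c(4, 4, 2))),
               "zero complete")
})

test_that("the system matrix is energy-scaled per wavelength", {
  Eeq <- buildSystemMatrix(pulseEnergies = c(2, 2, 2))
  raw <- extinctionCoefficients()
  expect_equal(unname(Eeq / raw), matrix(2, 3, 3), tolerance = 1e-12)
  E2 <- buildSystemMatrix(pulseEnergies = c(1, 2, 1))
  expect_equal(unname(E2[2, ] / raw[2, ]), rep(2, 3), tolerance = 1e-12)
  expect_equal(unname(E2[1, ] / raw[1, ]), rep(1, 3), tolerance = 1e-12)
  # the embedded 750/800/850 matrix is invertible with finite conditioning
  expect_true(is.finite(kappa(buildSystemMatrix())))
  expect_lt(kappa(buildSystemMatrix()), 1e6)
  badTable <- extinctionCoefficients()[, 1:2]
  expect_error(buildSystemMatrix(table = badTable), "HbO, HbD, ICG")
})

test_that("NNLS unmixing solves exact forward models and clips infeasible fits", {
  E <- buildSystemMatrix()
  p <- as.numeric(E %*% c(1, 0, 0))
  imgs <- array(rep(p, each = 4), dim = c(2, 2, 3))
  cm <- unmixStack(imgs, E)
  expect_equal(hbo(cm)[1, 1], 1, tolerance = 1e-8)
  expect_equal(hbd(cm)[1, 1], 0, tolerance = 1e-8)
  expect_equal(icg(cm)[1, 1], 0, tolerance = 1e-8)
  # all-negative data: the non-negative fit collapses to zero
  cmNeg <- unmixStack(array(rep(-p, each = 4), dim = c(2, 2, 3)), E)
  expect_equal(unname(hbo(cmNeg)), matrix(0, 2, 2))
  expect_equal(unname(hbd(cmNeg)), matrix(0, 2, 2))
  expect_equal(unname(icg(cmNeg)), matrix(0, 2, 2))
  expect_equal(fitResidual(cmNeg)[1, 1], sqrt(sum(p^2)), tolerance = 1e-10)
})

test_that("NNLS beats a 50^3 brute-force grid on its own objective", {
  set.seed(4)
  E <- buildSystemMatrix()
  scales <- c(1, 1, 5e-3)  # chromophore magnitudes spanned by the grid
  grid <- as.matrix(expand.grid(seq(0, scales[1], length.out = 50),
                                seq(0, scales[2], length.out = 50),
                                seq(0, scales[3], length.out = 50)))
  pred <- grid %*% t(E)
  for (i in 1:8) {
    cTrue <- c(runif(2, 0, 1), runif(1, 0, 5e-3))
    p <- as.numeric(E %*% cTrue) + rnorm(3, sd = 20)
    cm <- unmixStack(array(rep(p, each = 1), dim = c(1, 1, 3)), E)
    objNnls <- sum((as.numeric(E %*% c(hbo(cm)[1, 1], hbd(cm)[1, 1],
                                       icg(cm)[1, 1])) - p)^2)
    objGrid <- min(rowSums((pred - matrix(p, nrow(pred), 3,
                                          byrow = TRUE))^2))
    expect_lte(objNnls, objGrid + 1e-8)
  }
})

test_that("SO2 maps follow HbO / (HbO + HbD) with a support floor", {
  cm <- new("ConcentrationMaps", hbo = matrix(c(1, 1, 0, 3), 2),
            hbd = matrix(c(1, 0, 0, 1), 2),
            icg = matrix(0, 2, 2), residual = matrix(0, 2, 2))
  s <- computeSo2(cm, floor = 0.1)
  expect_equal(s@so2[1, 1], 0.5)
  expect_equal(s@so2[2, 1], 1.0)
  expect_true(is.na(s@so2[1, 2]))     # HbO = HbD = 0: masked
  expect_false(supportMask(s)[1, 2])
  # invariant to joint rescaling of the hemoglobins
  cm2 <- cm; cm2@hbo <- 7 * cm@hbo; cm2@hbd <- 7 * cm@hbd
  s2 <- computeSo2(cm2, floor = 0.1)
  expect_equal(s2@so2[supportMask(s2)], s@so2[supportMask(s)])
})

test_that("concentrations are invariant under joint energy and image rescaling", {
  set.seed(5)
  imgs <- array(abs(rnorm(4 * 4 * 3, 500, 200)), dim = c(4, 4, 3))
  E1 <- buildSystemMatrix(pulseEnergies = c(1, 1.3, 0.8))
  E2 <- buildSystemMatrix(pulseEnergies = 2.5 * c(1, 1.3, 0.8))
  c1 <- unmixStack(imgs, E1)
  c2 <- unmixStack(2.5 * imgs, E2)
  expect_equal(hbo(c2), hbo(c1), tolerance = 1e-8)
  expect_equal(hbd(c2), hbd(c1), tolerance = 1e-8)
  expect_equal(icg(c2), icg(c1), tolerance = 1e-8)
})

test_that("end-to-end recovery at 30 dB SNR meets the SO2 and ICG accuracy floors", {
  set.seed(30)
  maes <- c(); icgErr <- c()
  for (rep in 1:4) {
    ph <- randomPhantom(16, 16, snrDb = 30)
    st <- simulateMspaStack(ph$phantom, seed = 100 + rep)$stack
    u <- unmixPAStack(st)
    so2T <- ph$hbo / (ph$hbo + ph$hbd)
    sup <- supportMask(u$so2)
    maes <- c(maes, mean(abs(so2(u$so2) - so2T)[sup]))
    hot <- ph$icg > 0.002
    icgErr <- c(icgErr, abs(mean(icg(u$concentrations)[hot]) /
                              mean(ph$icg[hot]) - 1))
  }
  expect_lt(mean(maes), 0.02)
  expect_lt(mean(icgErr), 0.05)
})

test_that("ICG time activity tracks a bolus and smooths as configured", {
  mk <- function(v) new("ConcentrationMaps", hbo = matrix(1, 3, 3),
                        hbd = matrix(1, 3, 3),
                        icg = matrix(v, 3, 3), residual = matrix(0, 3, 3))
  flat <- icgTimeActivity(lapply(rep(2, 6), mk), matrix(TRUE, 3, 3))
  expect_equal(seriesValues(flat$raw), rep(2, 6))
  # gamma-variate bolus peaking at a known frame
  tpts <- 0:29
  bolus <- dgamma(tpts, shape = 4, rate = 0.5)
  series <- icgTimeActivity(lapply(bolus, mk), matrix(TRUE, 3, 3),
                            smoothWindow = 3L)
  expect_lte(abs(which.max(seriesValues(series$raw)) -
                   (which.max(bolus))), 1)
  # window 1: smoothed equals raw
  s1 <- icgTimeActivity(lapply(bolus, mk), matrix(TRUE, 3, 3),
                        smoothWindow = 1L)
  expect_identical(seriesValues(s1$smoothed), seriesValues(s1$raw))
  expect_error(icgTimeActivity(lapply(rep(1, 3), mk),
                               matrix(FALSE, 3, 3)), "empty")
  expect_error(icgTimeActivity(list(mk(1)), matrix(TRUE, 3, 3)),
               "2 time points")
})

test_that("ICG display compression references the map maximum", {
  cm <- new("ConcentrationMaps", hbo = matrix(0, 2, 2),
            hbd = matrix(0, 2, 2), icg = matrix(c(10, 1, 0.1, 0), 2),
            residual = matrix(0, 2, 2))
  db <- icgDb(cm)
  expect_equal(db[1, 1], 0)
  expect_equal(db[2, 1], -20, tolerance = 1e-10)
})
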