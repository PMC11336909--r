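test_that("relative change reproduces the printed baseline/stimulated pairs", {
  pair <- function(base, stim)
    percentChange(relativeChange(c(rep(base, 10), stim)))[11]
  expect_equal(round(pair(9.5, 12.5), 1), 31.6)
  expect_equal(round(pair(9.0, 11.3), 1), 25.6)
  expect_equal(round(pair(6.0, 11.5), 1), 91.7)
  expect_equal(round(pair(4.5, 10.0), 1), 122.2)
})

test_that("relative change is zero for constant series and scale-invariant", {
  expect_equal(percentChange(relativeChange(rep(7.3, 25))), rep(0, 25))
  set.seed(2)
  x <- runif(30, 5, 10)
  expect_equal(percentChange(relativeChange(x)),
               percentChange(relativeChange(100 * x)), tolerance = 1e-10)
  # zero baseline: series flagged undefined
  und <- relativeChange(c(rep(0, 10), 1, 2))
  expect_true(all(is.na(percentChange(und))))
  expect_error(relativeChange(1:5, baselineN = 10L), "shorter")
})

test_that("ROI time courses average pixels with the closed-form two-pixel sd", {
  a <- sin(1:20); b <- cos(1:20)
  stack <- array(0, dim = c(2, 1, 20))
  stack[1, 1, ] <- a; stack[2, 1, ] <- b
  ts <- roiTimecourse(stack, matrix(TRUE, 2, 1))
  expect_equal(seriesValues(ts), (a + b) / 2)
  expect_equal(ts@sdValues, abs(a - b) / sqrt(2), tolerance = 1e-12)
  # single-pixel mask: the pixel's own trace
  ts1 <- roiTimecourse(stack, matrix(c(TRUE, FALSE), 2, 1))
  expect_equal(seriesValues(ts1), a)
  # uniform stack: zero sd
  u <- array(5, dim = c(3, 3, 7))
  expect_equal(roiTimecourse(u, matrix(TRUE, 3, 3))@sdValues, rep(0, 7))
  expect_error(roiTimecourse(stack, matrix(FALSE, 2, 1)), "empty")
})

test_that("pixelwise relative change is computed before ROI averaging", {
  stack <- array(0, dim = c(2, 1, 12))
  stack[1, 1, ] <- c(rep(2, 10), 4, 4)    # +100%
  stack[2, 1, ] <- c(rep(10, 10), 15, 15) # +50%
  rs <- roiRelativeTimecourse(stack, matrix(TRUE, 2, 1), baselineN = 10L)
  # mean of per-pixel changes, not change of the mean (which would be 58%)
  expect_equal(percentChange(rs)[11], 75)
  expect_equal(rs@sdPercent[11], sd(c(100, 50)))
})

test_that("voxelwise cross-correlation detects exact shifts and anti-correlation", {
  set.seed(3)
  ref <- as.numeric(arima.sim(list(ar = 0.7), 120))
  stack <- array(rnorm(4 * 120), dim = c(2, 2, 120))
  stack[1, 1, ] <- ref
  stack[1, 2, ] <- c(rep(0, 2), ref[1:118])   # ref delayed 2 frames
  stack[2, 1, ] <- -ref
  refMask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  cc <- crosscorrMap(stack, refMask, maxLag = 5, framePeriod = 0.71)
  lag0 <- which(cc@lags == 0L)
  expect_equal(corrValues(cc)[1, 1, lag0], 1, tolerance = 1e-12)
  expect_equal(corrValues(cc)[2, 1, lag0], -1, tolerance = 1e-12)
  shifted <- corrValues(cc)[1, 2, ]
  expect_identical(cc@lags[which.max(shifted)], 2L)
  expect_gt(max(shifted), 0.999)
  # lag axis in seconds
  expect_equal(lagSeconds(cc), (-5:5) * 0.71)
  # zero-variance voxel masked
  stack[2, 2, ] <- 3
  cc2 <- crosscorrMap(stack, refMask, maxLag = 2)
  expect_true(all(is.na(corrValues(cc2)[2, 2, ])))
  expect_error(crosscorrMap(stack, refMask, maxLag = 60), "twice")
})

test_that("cross-correlation is symmetric in its arguments with reversed lag", {
  set.seed(4)
  stack <- array(rnorm(9 * 80), dim = c(3, 3, 80))
  a <- matrix(FALSE, 3, 3); a[1, 1] <- TRUE
  b <- matrix(FALSE, 3, 3); b[3, 3] <- TRUE
  ab <- corrValues(roiPairCrosscorr(stack, a, b, maxLag = 6))[1, 1, ]
  ba <- corrValues(roiPairCrosscorr(stack, b, a, maxLag = 6))[1, 1, ]
  expect_equal(ab, rev(ba), tolerance = 1e-12)
  expect_true(all(abs(c(ab, ba)) <= 1 + 1e-12))
})

test_that("ROI-pair correlation finds sinusoid phase relations and the vein trough", {
  t <- 0:199
  period <- 20
  s1 <- sin(2 * pi * t / period)
  s2 <- sin(2 * pi * (t - period / 2) / period)   # half-period shift
  stack <- array(0, dim = c(2, 1, 200))
  stack[1, 1, ] <- s1; stack[2, 1, ] <- s2
  a <- matrix(c(TRUE, FALSE), 2, 1); b <- matrix(c(FALSE, TRUE), 2, 1)
  cc <- roiPairCrosscorr(stack, a, b, maxLag = 15)
  r <- corrValues(cc)[1, 1, ]
  expect_equal(r[cc@lags == 0], -1, tolerance = 0.01)
  expect_equal(r[cc@lags == period / 2], 1, tolerance = 0.01)
  # identical ROIs: peak R = 1 at zero lag
  ccSelf <- roiPairCrosscorr(stack, a, a, maxLag = 5)
  expect_equal(attr(ccSelf, "peakLag"), 0)
  # anti-phase "vein" delayed 2 frames at 0.71 s/frame: trough at +1.42 s
  set.seed(5)
  ref <- as.numeric(arima.sim(list(ar = 0.8), 150))
  vein <- c(rep(0, 2), -ref[1:148])
  stack2 <- array(0, dim = c(2, 1, 150))
  stack2[1, 1, ] <- ref; stack2[2, 1, ] <- vein
  ccV <- roiPairCrosscorr(stack2, a, b, maxLag = 8, framePeriod = 0.71)
  expect_equal(attr(ccV, "troughLag"), 1.42, tolerance = 1e-12)
})

test_that("paradigm summaries report window means and peak timing", {
  # step response aligned to the stimulus window
  dt <- 12
  rs <- new("RelativeSeries",
            percent = c(rep(0, 10), rep(40, 15), rep(10, 15)),
            baselineMean = 1, framePeriod = dt, sdPercent = numeric())
  ps <- paradigmSummary(rs)
  expect_equal(ps$baselineMean, 0)
  expect_equal(ps$stimulusMean, 40)
  expect_equal(ps$postMean, 10)
  # flat series: all windows equal
  flat <- new("RelativeSeries", percent = rep(3, 40), baselineMean = 1,
              framePeriod = dt, sdPercent = numeric())
  pf <- paradigmSummary(flat)
  expect_equal(pf$baselineMean, pf$stimulusMean)
  expect_equal(pf$stimulusMean, pf$postMean)
  # ramp during stimulation: peak at the end of the stimulus window
  ramp <- new("RelativeSeries",
              percent = c(rep(0, 10), seq(1, 30, length.out = 15),
                          rep(0, 15)),
              baselineMean = 1, framePeriod = dt, sdPercent = numeric())
  pr <- paradigmSummary(ramp)
  expect_equal(pr$peakTime, 25 * dt - 10 * dt - dt / 2)
  expect_error(paradigmSummary(
    new("RelativeSeries", percent = rep(0, 5), baselineMean = 1,
        framePeriod = dt, sdPercent = numeric())), "shorter")
})
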