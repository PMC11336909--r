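test_that("compounded-frame period and acquisition window are exact", {
  sched <- planUfusBlock(ufusSequenceParams())
  expect_identical(framePeriod(sched, "us"), 525)
  expect_identical(acquisitionWindow(sched, "us"), 78750)
  expect_equal(acquisitionWindow(sched), 0.07875)
  # exact integer arithmetic: window = n_frames x period with no drift
  expect_identical(acquisitionWindow(sched, "us"),
                   150 * framePeriod(sched, "us"))
  # single-angle, single-frame degenerate case
  p1 <- ufusSequenceParams(angleList = 0, interAngleInterval = 100e-6,
                           nCompoundFrames = 1L)
  s1 <- planUfusBlock(p1)
  expect_identical(framePeriod(s1, "us"), 100)
  expect_identical(acquisitionWindow(s1, "us"), 100)
})

test_that("photoacoustic block timing and wavelength cycling are exact", {
  sched <- planMspaBlock(mspaSequenceParams())
  ev <- scheduleEvents(sched)
  expect_identical(nrow(ev), 16L)
  expect_equal(acquisitionWindow(sched), 1.6)
  # wavelengths cycle 750 -> 800 -> 850; frame 4 restarts the cycle
  expect_identical(ev$wavelength[1:4], c(750, 800, 850, 750))
  # linear scaling: one set, no spare
  s1 <- planMspaBlock(mspaSequenceParams(nSets = 1L, nSpareFrames = 0L))
  expect_equal(acquisitionWindow(s1), 0.3)
})

test_that("localization-microscopy session timing is exact", {
  p <- ufusSequenceParams(interAngleInterval = 200e-6,
                          nCompoundFrames = 400L, transferTime = 2,
                          syncSlack = 0)
  perSeq <- planUfusBlock(p)
  expect_equal(acquisitionWindow(perSeq), 0.56)
  sess <- planUlmSession(p, 300L)
  expect_equal(acquisitionWindow(sess), 168)
  # transfer gaps count toward the session duration, not the accumulation
  expect_equal(blockDuration(sess), 300 * (0.56 + 2))
  s1 <- planUlmSession(ufusSequenceParams(nCompoundFrames = 1L), 1L)
  expect_identical(acquisitionWindow(s1, "us"), framePeriod(s1, "us"))
})

test_that("schedules are idempotent and validated", {
  p <- ufusSequenceParams()
  expect_identical(scheduleEvents(planUfusBlock(p)),
                   scheduleEvents(planUfusBlock(p)))
  expect_error(ufusSequenceParams(angleList = numeric(0)), "non-empty")
  expect_error(mspaSequenceParams(laserPrf = 0), "positive")
  expect_error(mspaSequenceParams(wavelengths = c(750, 750, 850)),
               "distinct")
  ev <- scheduleEvents(planMspaBlock(mspaSequenceParams()))
  expect_true(all(diff(ev$startUs) > 0))
})

test_that("schedules export as CSV event tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  exportSchedule(planUfusBlock(ufusSequenceParams()), path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 150L)
  expect_true(all(c("label", "startUs", "startSeconds") %in% names(tab)))
  expect_equal(tab$startSeconds[2], 525e-6)
})
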