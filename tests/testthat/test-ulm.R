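test_that("sub-pixel localization is exact on noiseless Gaussian PSFs", {
  tr <- trackSet(list(data.frame(frame = 1, z = 10.3, x = 20.7)))
  fr <- simulateMbMovie(tr, psfSigma = 1.3, frameShape = c(32, 32))$frames
  loc <- localizeMbs(fr[, , 1], 0.3)
  expect_identical(nrow(loc), 1L)
  expect_lt(sqrt((loc$z - 10.3)^2 + (loc$x - 20.7)^2), 0.05)
  # blank frame: empty list
  expect_identical(nrow(localizeMbs(matrix(0, 16, 16), 0.5)), 0L)
  # two PSFs far apart: exactly two localizations
  tr2 <- trackSet(list(data.frame(frame = 1, z = 8.2, x = 10.5),
                       data.frame(frame = 1, z = 18.7, x = 10.5)))
  fr2 <- simulateMbMovie(tr2, psfSigma = 1.3,
                         frameShape = c(32, 32))$frames
  expect_identical(nrow(localizeMbs(fr2[, , 1], 0.3)), 2L)
})

test_that("localization stays within 0.3 px at 20 dB SNR", {
  set.seed(6)
  errs <- replicate(40, {
    zx <- runif(2, 10, 20)
    fr <- simulateMbMovie(
      trackSet(list(data.frame(frame = 1, z = zx[1], x = zx[2]))),
      psfSigma = 1.3, frameShape = c(32, 32), noiseSigma = 0.1,
      seed = sample.int(1e6, 1))$frames
    loc <- localizeMbs(fr[, , 1], 0.5)
    if (nrow(loc) < 1) NA else
      min(sqrt((loc$z - zx[1])^2 + (loc$x - zx[2])^2))
  })
  expect_false(anyNA(errs))
  expect_lt(mean(errs), 0.3)
})

test_that("frame-to-frame linking forms unambiguous tracks and filters short ones", {
  # one bubble at 1 px/frame for 30 frames: one full-length track
  dets <- lapply(1:30, function(f)
    data.frame(z = 5 + f, x = 12, amp = 1))
  ts <- linkTracks(dets, maxLinkDistance = 2, minTrackLength = 20L)
  expect_identical(nTracks(ts), 1L)
  expect_identical(nrow(tracks(ts)[[1]]), 30L)
  expect_true(all(diff(tracks(ts)[[1]]$frame) == 1L))
  # a track one frame short of the minimum is discarded
  short <- lapply(1:19, function(f) data.frame(z = 5 + f, x = 12, amp = 1))
  expect_identical(nTracks(linkTracks(short, 2, minTrackLength = 20L)), 0L)
  expect_identical(
    nTracks(linkTracks(short, 2, minTrackLength = 19L)), 1L)
})

test_that("crossing-bubble assignment equals the brute-force minimum-cost matching", {
  prev <- data.frame(z = c(10, 20), x = c(10, 10), amp = 1)
  nxt <- data.frame(z = c(12.5, 18), x = c(10, 10), amp = 1)
  D <- sqrt(outer(prev$z, nxt$z, "-")^2 + outer(prev$x, nxt$x, "-")^2)
  bf <- bruteForceAssign(D)
  ts <- linkTracks(list(prev, nxt), maxLinkDistance = 5,
                   minTrackLength = 2L)
  expect_identical(nTracks(ts), 2L)
  linkCost <- sum(vapply(tracks(ts), function(tr)
    sqrt(diff(tr$z)^2 + diff(tr$x)^2), numeric(1)))
  expect_equal(linkCost, bf$cost, tolerance = 1e-10)
  # links beyond the gate are refused: both detections start new tracks
  far <- linkTracks(list(data.frame(z = 5, x = 5, amp = 1),
                         data.frame(z = 30, x = 30, amp = 1)),
                    maxLinkDistance = 2, minTrackLength = 1L)
  expect_identical(nTracks(far), 2L)
  expect_true(all(vapply(tracks(far), nrow, integer(1)) == 1L))
})

test_that("accumulated maps count localizations and average step speeds", {
  # 0.714 px/frame at 714.29 Hz with 0.01 mm pixels: 5.10 mm/s
  trk <- trackSet(list(linearTrack(c(5, 20), c(0.714, 0), 50)),
                  framePeriod = 1 / 714.29, pixelPitch = 0.01)
  maps <- accumulateMaps(trk, gridPitch = 0.01, frameShape = c(64, 64))
  sp <- meanSpeed(maps)[!is.na(meanSpeed(maps))]
  expect_equal(unique(round(sp, 6)), round(0.714 * 0.01 * 714.29, 6),
               tolerance = 1e-6)
  expect_identical(sum(density_map(maps)), 50)
  expect_true(all(directionCoded(maps)[density_map(maps) > 0] > 0))
  # stationary bubble: zero speed, all counts in one bin
  still <- trackSet(list(data.frame(frame = 1:12, z = 7, x = 9,
                                    amp = 1)), framePeriod = 1 / 714.29,
                    pixelPitch = 0.01)
  ms <- accumulateMaps(still, 0.01, c(20, 20))
  expect_identical(max(density_map(ms)), 12)
  expect_identical(sum(density_map(ms) > 0), 1L)
  expect_equal(meanSpeed(ms)[density_map(ms) > 0], 0)
  # ascending track: negative direction coding
  up <- trackSet(list(linearTrack(c(30, 10), c(-0.5, 0), 20)),
                 framePeriod = 1 / 714.29, pixelPitch = 0.01)
  mu <- accumulateMaps(up, 0.01, c(40, 20))
  expect_true(all(directionCoded(mu)[density_map(mu) > 0] < 0))
  expect_error(accumulateMaps(trk, gridPitch = 0), "positive")
})

test_that("vessels two super-resolution bins apart resolve into distinct ridges", {
  mk <- function(x0, f0) data.frame(frame = f0:(f0 + 29),
                                    z = seq(5, 25, length.out = 30),
                                    x = x0, amp = 1)
  tall <- trackSet(list(mk(20.0, 1), mk(20.2, 31)),
                   framePeriod = 1 / 714.29, pixelPitch = 0.1)
  mv <- simulateMbMovie(tall, psfSigma = 1.3, frameShape = c(32, 40),
                        nFrames = 60)
  res <- ulmPipeline(mv$frames, detectionThreshold = 0.3,
                     minTrackLength = 10L, gridPitch = 0.01,
                     framePeriod = 1 / 714.29, pixelPitch = 0.1)
  prof <- colSums(density_map(res$maps))
  occupied <- which(prof > 0)
  # two ridges separated by exactly 2 bins (20 um) despite the 1.3 px PSF
  expect_identical(length(occupied), 2L)
  expect_identical(diff(occupied), 2L)
})

test_that("per-bin speed recovery stays within 5% across seeds", {
  set.seed(9)
  relErr <- replicate(10, {
    speed <- runif(1, 2, 8)                       # mm/s
    stepPx <- speed / (714.29 * 0.01)             # px per frame
    z0 <- runif(1, 4, 8)
    trk <- trackSet(list(linearTrack(c(z0, 15), c(stepPx, 0), 30)),
                    framePeriod = 1 / 714.29, pixelPitch = 0.01)
    mv <- simulateMbMovie(trk, psfSigma = 1.3, frameShape = c(48, 32),
                          noiseSigma = 0.05, seed = sample.int(1e6, 1))
    res <- ulmPipeline(mv$frames, detectionThreshold = 0.4,
                       minTrackLength = 15L, gridPitch = 0.01,
                       framePeriod = 1 / 714.29, pixelPitch = 0.01)
    abs(mean(meanSpeed(res$maps), na.rm = TRUE) - speed) / speed
  })
  expect_lt(median(relErr), 0.05)
})
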