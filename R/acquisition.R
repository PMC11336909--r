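## Deterministic timing model of the interleaved dual-modality acquisition.
## All arithmetic is done in whole microseconds so that quantities such as a
## 525 us compound-frame period and the resulting 78.75 ms acquisition
## window are exact, with no float accumulation across events.

.secToUs <- function(s) {
  us <- s * 1e6
  if (abs(us - round(us)) > 1e-6)
    stop("time ", s, " s is not representable in whole microseconds")
  round(us)
}

#' Plan one ultrafast-ultrasound compounding block
#'
#' One compounded frame is formed per full cycle of the tilt-angle list, so
#' the compound-frame period equals \code{length(angleList) *
#' interAngleInterval}; the acquisition window is that period times the
#' number of compounded frames, and the block duration additionally includes
#' the host transfer time and trigger-synchronization slack. With the
#' defaults (7 angles, 75 us apart, 150 frames) this gives a 525 us frame
#' period and a 78.75 ms acquisition window per blood-volume map.
#'
#' @param params a \code{\link{ufusSequenceParams}} object.
#' @return A \code{\link{FrameSchedule}} whose events list every compounded
#'   frame start.
#' @examples
#' sched <- planUfusBlock(ufusSequenceParams())
#' framePeriod(sched, "us")        # 525
#' acquisitionWindow(sched, "us")  # 78750
#' @export
planUfusBlock <- function(params) {
  validObject(params)
  periodUs <- length(params@angleList) * .secToUs(params@interAngleInterval)
  nf <- params@nCompoundFrames
  windowUs <- nf * periodUs
  blockUs <- windowUs + .secToUs(params@transferTime) +
    .secToUs(params@syncSlack)
  ev <- data.frame(
    label = sprintf("compound_frame_%03d", seq_len(nf)),
    startUs = (seq_len(nf) - 1L) * periodUs)
  new("FrameSchedule", framePeriodUs = periodUs,
      acquisitionWindowUs = windowUs, blockDurationUs = blockUs, events = ev)
}

#' Plan one multispectral photoacoustic block
#'
#' Frames fire at the laser pulse repetition frequency, cycling through the
#' wavelength list; a block holds \code{nSets} complete wavelength sets plus
#' \code{nSpareFrames} guard frames. With the defaults (5 sets of 750, 800,
#' 850 nm plus one spare at 10 Hz) the block comprises 16 frames in 1.6 s.
#'
#' @param params a \code{\link{mspaSequenceParams}} object.
#' @return A \code{\link{FrameSchedule}}; each event label carries the
#'   wavelength assignment of its frame.
#' @examples
#' sched <- planMspaBlock(mspaSequenceParams())
#' acquisitionWindow(sched)  # 1.6
#' @export
planMspaBlock <- function(params) {
  validObject(params)
  if (params@laserPrf <= 0) stop("laserPrf must be positive")
  periodUs <- .secToUs(1 / params@laserPrf)
  nwl <- length(params@wavelengths)
  nf <- params@nSets * nwl + params@nSpareFrames
  windowUs <- nf * periodUs
  blockUs <- windowUs + .secToUs(params@transferTime)
  wl <- params@wavelengths[((seq_len(nf) - 1L) %% nwl) + 1L]
  ev <- data.frame(
    label = sprintf("pa_frame_%02d_%dnm", seq_len(nf), wl),
    startUs = (seq_len(nf) - 1L) * periodUs,
    wavelength = wl)
  new("FrameSchedule", framePeriodUs = periodUs,
      acquisitionWindowUs = windowUs, blockDurationUs = blockUs, events = ev)
}

#' Plan a microbubble localization-microscopy session
#'
#' A session repeats the compounding sequence \code{nSequences} times. The
#' accumulation time counts only active acquisition (data-transfer gaps are
#' excluded), while the block duration counts the whole session including
#' transfer gaps. With 7 angles 200 us apart and 400 frames, one sequence
#' spans 560 ms; 300 sequences accumulate 168 s of microbubble data.
#'
#' @param params a \code{\link{ufusSequenceParams}} object (typically 200 us
#'   between angles and 400 compounded frames).
#' @param nSequences number of repeated sequences.
#' @return A \code{\link{FrameSchedule}} with one event per sequence;
#'   \code{acquisitionWindow} is the total accumulation time and
#'   \code{blockDuration} the total session time.
#' @examples
#' p <- ufusSequenceParams(interAngleInterval = 200e-6,
#'                         nCompoundFrames = 400L, transferTime = 2,
#'                         syncSlack = 0)
#' sched <- planUlmSession(p, 300L)
#' acquisitionWindow(sched)  # 168
#' @export
planUlmSession <- function(params, nSequences) {
  validObject(params)
  nSequences <- as.integer(nSequences)
  if (nSequences < 1L) stop("nSequences must be >= 1")
  perSeq <- planUfusBlock(params)
  seqAcqUs <- perSeq@acquisitionWindowUs
  seqBlockUs <- perSeq@blockDurationUs
  ev <- data.frame(
    label = sprintf("sequence_%03d", seq_len(nSequences)),
    startUs = (seq_len(nSequences) - 1L) * seqBlockUs)
  new("FrameSchedule", framePeriodUs = perSeq@framePeriodUs,
      acquisitionWindowUs = nSequences * seqAcqUs,
      blockDurationUs = nSequences * seqBlockUs, events = ev)
}

#' Export a frame schedule as a CSV event table
#'
#' @param schedule a \code{FrameSchedule}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
exportSchedule <- function(schedule, path) {
  ev <- schedule@events
  ev$startSeconds <- ev$startUs / 1e6
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
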