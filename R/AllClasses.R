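#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition sequence parameters and schedules
## ---------------------------------------------------------------------------

#' Ultrafast-ultrasound sequence parameters
#'
#' Parameters of a plane-wave compounding sequence: the set of transmit tilt
#' angles, the time between successive angled transmissions, the number of
#' compounded frames per block, and the block's host-transfer time.
#'
#' @slot angleList numeric, plane-wave tilt angles in degrees.
#' @slot interAngleInterval numeric(1), seconds between angled transmissions.
#' @slot nCompoundFrames integer(1), compounded frames per acquisition block.
#' @slot transferTime numeric(1), seconds of host data transfer per block.
#' @slot syncSlack numeric(1), seconds of trigger-synchronization idle
#'   appended to each block (configurable; nominally about 0.2 s).
#' @export
setClass("UfusSequenceParams",
  representation(angleList = "numeric", interAngleInterval = "numeric",
                 nCompoundFrames = "integer", transferTime = "numeric",
                 syncSlack = "numeric"))

setValidity("UfusSequenceParams", function(object) {
  msg <- character()
  if (length(object@angleList) == 0L)
    msg <- c(msg, "angleList must be non-empty")
  if (length(object@interAngleInterval) != 1L || object@interAngleInterval <= 0)
    msg <- c(msg, "interAngleInterval must be a single positive number")
  if (length(object@nCompoundFrames) != 1L || object@nCompoundFrames < 1L)
    msg <- c(msg, "nCompoundFrames must be >= 1")
  if (object@transferTime < 0 || object@syncSlack < 0)
    msg <- c(msg, "transferTime and syncSlack must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param angleList numeric vector of tilt angles (degrees).
#' @param interAngleInterval seconds between angles.
#' @param nCompoundFrames compounded frames per block.
#' @param transferTime seconds of data transfer appended to the block.
#' @param syncSlack seconds of trigger-synchronization idle per block.
#' @return A \code{UfusSequenceParams} object.
#' @examples
#' ufusSequenceParams()  # 7 angles, 75 us apart, 150 frames
#' @rdname UfusSequenceParams-class
#' @export
ufusSequenceParams <- function(angleList = seq(-6, 6, by = 2),
                               interAngleInterval = 75e-6,
                               nCompoundFrames = 150L,
                               transferTime = 1.1,
                               syncSlack = 0.2) {
  new("UfusSequenceParams", angleList = angleList,
      interAngleInterval = interAngleInterval,
      nCompoundFrames = as.integer(nCompoundFrames),
      transferTime = transferTime, syncSlack = syncSlack)
}

#' Multispectral photoacoustic sequence parameters
#'
#' @slot laserPrf numeric(1), laser pulse repetition frequency in Hz.
#' @slot wavelengths numeric, optical wavelengths in nm, cycled in order.
#' @slot nSets integer(1), number of complete wavelength sets per block.
#' @slot nSpareFrames integer(1), extra frames guarding against trigger loss.
#' @slot transferTime numeric(1), seconds of host transfer per block.
#' @export
setClass("MspaSequenceParams",
  representation(laserPrf = "numeric", wavelengths = "numeric",
                 nSets = "integer", nSpareFrames = "integer",
                 transferTime = "numeric"))

setValidity("MspaSequenceParams", function(object) {
  msg <- character()
  if (length(object@laserPrf) != 1L || object@laserPrf <= 0)
    msg <- c(msg, "laserPrf must be a single positive number")
  if (anyDuplicated(object@wavelengths))
    msg <- c(msg, "wavelengths must be distinct")
  if (length(object@wavelengths) == 0L)
    msg <- c(msg, "wavelengths must be non-empty")
  if (object@nSets < 1L) msg <- c(msg, "nSets must be >= 1")
  if (object@nSpareFrames < 0L) msg <- c(msg, "nSpareFrames must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param laserPrf laser pulse repetition frequency (Hz).
#' @param wavelengths wavelengths in nm, in firing order.
#' @param nSets complete wavelength sets per block.
#' @param nSpareFrames spare frames per block.
#' @param transferTime seconds of data transfer per block.
#' @return A \code{MspaSequenceParams} object.
#' @rdname MspaSequenceParams-class
#' @export
mspaSequenceParams <- function(laserPrf = 10,
                               wavelengths = c(750, 800, 850),
                               nSets = 5L, nSpareFrames = 1L,
                               transferTime = 0.3) {
  new("MspaSequenceParams", laserPrf = laserPrf, wavelengths = wavelengths,
      nSets = as.integer(nSets), nSpareFrames = as.integer(nSpareFrames),
      transferTime = transferTime)
}

#' Frame schedule of an acquisition block
#'
#' Times are carried internally in integer microseconds so that sequence
#' arithmetic (e.g. a 525 us compound period giving a 78.75 ms window) is
#' exact; accessors return seconds.
#'
#' @slot framePeriodUs numeric(1), whole microseconds per frame.
#' @slot acquisitionWindowUs numeric(1), whole microseconds of active
#'   acquisition in the block.
#' @slot blockDurationUs numeric(1), acquisition window plus transfer (and
#'   any idle slack), microseconds.
#' @slot events data.frame with columns \code{label} and \code{startUs}.
#' @export
setClass("FrameSchedule",
  representation(framePeriodUs = "numeric", acquisitionWindowUs = "numeric",
                 blockDurationUs = "numeric", events = "data.frame"))

setValidity("FrameSchedule", function(object) {
  msg <- character()
  if (object@framePeriodUs < 0 || object@acquisitionWindowUs < 0 ||
      object@blockDurationUs < 0)
    msg <- c(msg, "durations must be non-negative")
  st <- object@events$startUs
  if (length(st) > 1L && any(diff(st) <= 0))
    msg <- c(msg, "event start times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## IQ movies and synthetic-scene specifications
## ---------------------------------------------------------------------------

#' Beamformed complex IQ movie
#'
#' A coherently compounded in-phase/quadrature frame stack with the
#' acquisition metadata needed for Doppler processing. Axis convention:
#' (depth z, lateral x, slow time t), depth increasing away from the
#' transducer.
#'
#' @slot data complex array (depth x lateral x slow-time).
#' @slot pixelPitch numeric(1), pixel spacing in mm (isotropic).
#' @slot f0 numeric(1), transmit center frequency in Hz.
#' @slot c numeric(1), speed of sound in m/s.
#' @slot prfc numeric(1), compounded frame rate in Hz.
#' @export
setClass("IQMovie",
  representation(data = "array", pixelPitch = "numeric", f0 = "numeric",
                 c = "numeric", prfc = "numeric"))

setValidity("IQMovie", function(object) {
  msg <- character()
  if (!is.complex(object@data)) msg <- c(msg, "data must be complex")
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array (depth, lateral, time)")
  else if (any(dim(object@data) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (object@prfc <= 0) msg <- c(msg, "prfc must be positive")
  if (object@f0 <= 0) msg <- c(msg, "f0 must be positive")
  if (object@c <= 0) msg <- c(msg, "c must be positive")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (length(msg)) msg else TRUE
})

#' @param data complex 3-D array (depth, lateral, slow time).
#' @param pixelPitch pixel spacing, mm.
#' @param f0 center frequency, Hz.
#' @param c sound speed, m/s.
#' @param prfc compounded frame rate, Hz.
#' @return An \code{IQMovie}.
#' @examples
#' m <- IQMovie(array(complex(real = rnorm(8), imaginary = rnorm(8)),
#'                    dim = c(2, 2, 2)))
#' prfc(m)
#' @rdname IQMovie-class
#' @export
IQMovie <- function(data, pixelPitch = 0.1, f0 = 15e6, c = 1540,
                    prfc = 1e6 / 525) {
  if (!is.complex(data)) storage.mode(data) <- "complex"
  new("IQMovie", data = data, pixelPitch = pixelPitch, f0 = f0, c = c,
      prfc = prfc)
}

#' Vessel specification for the IQ simulator
#'
#' @slot center numeric(2), (depth mm, lateral mm) of the vessel axis center.
#' @slot radius numeric(1), vessel radius in mm.
#' @slot axialVelocity numeric(1), signed axial blood speed in mm/s;
#'   positive = descending (away from the transducer).
#' @slot scattererDensity numeric(1), scatterers per mm^2.
#' @slot orientation character(1), one of "axial", "lateral" or "angled".
#' @slot angle numeric(1), degrees from vertical when orientation = "angled".
#' @slot profile character(1), lumen flow profile: "parabolic" (laminar
#'   Poiseuille, \code{axialVelocity} is the centerline peak) or "plug".
#' @export
setClass("VesselSpec",
  representation(center = "numeric", radius = "numeric",
                 axialVelocity = "numeric", scattererDensity = "numeric",
                 orientation = "character", angle = "numeric",
                 profile = "character"))

setValidity("VesselSpec", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be positive")
  if (object@scattererDensity <= 0) msg <- c(msg, "scattererDensity must be positive")
  if (!object@orientation %in% c("axial", "lateral", "angled"))
    msg <- c(msg, "orientation must be 'axial', 'lateral' or 'angled'")
  if (!object@profile %in% c("parabolic", "plug"))
    msg <- c(msg, "profile must be 'parabolic' or 'plug'")
  if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
  if (length(msg)) msg else TRUE
})

#' @param center (depth mm, lateral mm).
#' @param radius vessel radius, mm.
#' @param axialVelocity signed axial speed, mm/s (+ = descending).
#' @param scattererDensity scatterers per mm^2.
#' @param orientation vessel axis orientation.
#' @param angle degrees from vertical for "angled" vessels.
#' @param profile "parabolic" or "plug" lumen flow profile.
#' @return A \code{VesselSpec}.
#' @rdname VesselSpec-class
#' @export
vesselSpec <- function(center, radius, axialVelocity,
                       scattererDensity = 300, orientation = "axial",
                       angle = 0, profile = "plug") {
  new("VesselSpec", center = as.numeric(center), radius = radius,
      axialVelocity = axialVelocity, scattererDensity = scattererDensity,
      orientation = orientation, angle = angle, profile = profile)
}

#' Tissue-clutter specification for the IQ simulator
#'
#' Clutter is an exact low-rank spatiotemporal process: \code{nModes} smooth
#' spatial patterns, each modulated by a band-limited temporal envelope.
#'
#' @slot amplitudeRatio numeric(1), clutter-to-blood linear amplitude ratio
#'   (e.g. 31.6 for clutter 30 dB above blood speckle).
#' @slot nModes integer(1), number of low-rank modes. The default of 10
#'   mirrors brain tissue motion rich enough that rejecting the first ten
#'   singular values removes it, as the processing chain assumes.
#' @slot modeBandwidth numeric(1), temporal bandwidth (hard band edge) of
#'   the envelopes, Hz. Over a window of T seconds a bandwidth B supports
#'   about 2 B T + 1 temporal degrees of freedom, so the bandwidth bounds
#'   the realizable clutter rank; the 30 Hz default (tissue moving below
#'   ~1.5 mm/s) sustains rank ~10 over 400-frame ensembles and keeps the
#'   tissue band clear of both the 70 Hz high-pass wall and the Doppler
#'   band of the slowest blood the chain is asked to resolve.
#' @slot modeDecay numeric(1) in (0, 1], geometric energy ratio between
#'   successive modes (decaying singular spectrum of tissue motion).
#' @export
setClass("ClutterSpec",
  representation(amplitudeRatio = "numeric", nModes = "integer",
                 modeBandwidth = "numeric", modeDecay = "numeric"))

setValidity("ClutterSpec", function(object) {
  msg <- character()
  if (object@amplitudeRatio < 0) msg <- c(msg, "amplitudeRatio must be >= 0")
  if (object@nModes < 1L) msg <- c(msg, "nModes must be >= 1")
  if (object@modeBandwidth <= 0) msg <- c(msg, "modeBandwidth must be positive")
  if (object@modeDecay <= 0 || object@modeDecay > 1)
    msg <- c(msg, "modeDecay must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param amplitudeDb clutter-to-blood amplitude ratio in dB (20 log10).
#' @param nModes number of low-rank modes.
#' @param modeBandwidth envelope bandwidth, Hz.
#' @param modeDecay geometric energy ratio between successive modes.
#' @return A \code{ClutterSpec}.
#' @rdname ClutterSpec-class
#' @export
clutterSpec <- function(amplitudeDb = 30, nModes = 10L, modeBandwidth = 30,
                        modeDecay = 0.6) {
  new("ClutterSpec", amplitudeRatio = 10^(amplitudeDb / 20),
      nModes = as.integer(nModes), modeBandwidth = modeBandwidth,
      modeDecay = modeDecay)
}

#' Chromophore phantom for the photoacoustic simulator
#'
#' @slot hbo,hbd,icg numeric matrices, per-pixel concentrations (arbitrary
#'   units, non-negative) of oxy-hemoglobin, deoxy-hemoglobin and
#'   indocyanine green.
#' @slot fluenceDecay numeric(1), effective attenuation (1/mm) of the
#'   exponential depth-dependent fluence.
#' @slot noiseSigma numeric(1), additive noise standard deviation in linear
#'   image units.
#' @slot pixelPitch numeric(1), mm per pixel (depth axis for fluence).
#' @export
setClass("ChromophorePhantom",
  representation(hbo = "matrix", hbd = "matrix", icg = "matrix",
                 fluenceDecay = "numeric", noiseSigma = "numeric",
                 pixelPitch = "numeric"))

setValidity("ChromophorePhantom", function(object) {
  msg <- character()
  d <- dim(object@hbo)
  if (!identical(d, dim(object@hbd)) || !identical(d, dim(object@icg)))
    msg <- c(msg, "hbo, hbd and icg maps must share dimensions")
  if (min(object@hbo, object@hbd, object@icg) < 0)
    msg <- c(msg, "concentrations must be non-negative")
  if (object@fluenceDecay < 0) msg <- c(msg, "fluenceDecay must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param hbo,hbd,icg concentration matrices (depth x lateral).
#' @param fluenceDecay exponential fluence coefficient, 1/mm.
#' @param noiseSigma additive noise sd, linear units.
#' @param pixelPitch mm per pixel.
#' @return A \code{ChromophorePhantom}.
#' @rdname ChromophorePhantom-class
#' @export
chromophorePhantom <- function(hbo, hbd, icg, fluenceDecay = 0,
                               noiseSigma = 0, pixelPitch = 0.1) {
  new("ChromophorePhantom", hbo = hbo, hbd = hbd, icg = icg,
      fluenceDecay = fluenceDecay, noiseSigma = noiseSigma,
      pixelPitch = pixelPitch)
}

#' Multispectral photoacoustic stack
#'
#' One amplitude image per (wavelength, repeat set), with the per-wavelength
#' laser pulse energies needed for energy normalization.
#'
#' @slot images numeric 4-D array (depth, lateral, wavelength, set).
#' @slot wavelengths numeric, nm.
#' @slot pulseEnergies numeric, mJ per wavelength.
#' @slot pixelPitch numeric(1), mm per pixel.
#' @export
setClass("PAStack",
  representation(images = "array", wavelengths = "numeric",
                 pulseEnergies = "numeric", pixelPitch = "numeric"))

setValidity("PAStack", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 4L)
    msg <- c(msg, "images must be 4-D (depth, lateral, wavelength, set)")
  else {
    if (d[3] != length(object@wavelengths))
      msg <- c(msg, "one image plane per wavelength required")
    if (length(object@pulseEnergies) != length(object@wavelengths))
      msg <- c(msg, "one pulse energy per wavelength required")
  }
  if (any(object@pulseEnergies <= 0))
    msg <- c(msg, "pulseEnergies must be positive")
  if (length(msg)) msg else TRUE
})

#' @param images 4-D array (depth, lateral, wavelength, set).
#' @param wavelengths nm.
#' @param pulseEnergies mJ per wavelength.
#' @param pixelPitch mm per pixel.
#' @return A \code{PAStack}.
#' @rdname PAStack-class
#' @export
PAStack <- function(images, wavelengths, pulseEnergies, pixelPitch = 0.1) {
  new("PAStack", images = images, wavelengths = wavelengths,
      pulseEnergies = pulseEnergies, pixelPitch = pixelPitch)
}

## ---------------------------------------------------------------------------
## Functional maps
## ---------------------------------------------------------------------------

#' Power-Doppler cerebral blood volume map
#'
#' @slot intensity numeric matrix, per-pixel mean squared IQ magnitude
#'   (linear units), the CBV proxy.
#' @slot nFramesUsed integer(1), slow-time frames averaged.
#' @export
setClass("CBVMap",
  representation(intensity = "matrix", nFramesUsed = "integer"))

setValidity("CBVMap", function(object) {
  if (any(object@intensity < 0)) "intensity must be non-negative" else TRUE
})

#' Signed axial velocity (cerebral blood flow) map
#'
#' Descending flow moves away from the transducer (deeper, displayed red);
#' ascending flow moves toward it (displayed blue). Velocities are zero
#' wherever the corresponding validity mask is \code{FALSE}, and are bounded
#' by the Nyquist velocity c * prfc / (4 f0).
#'
#' @slot vDescending,vAscending numeric matrices, mm/s, non-negative.
#' @slot validPos,validNeg logical matrices, validity of the positive- and
#'   negative-frequency directional components.
#' @slot vSigned numeric matrix, + descending, - ascending; where both
#'   directions are valid the larger-magnitude component wins.
#' @export
setClass("VelocityMap",
  representation(vDescending = "matrix", vAscending = "matrix",
                 validPos = "matrix", validNeg = "matrix",
                 vSigned = "matrix"))

setValidity("VelocityMap", function(object) {
  msg <- character()
  if (any(object@vDescending < 0) || any(object@vAscending < 0))
    msg <- c(msg, "per-direction velocities must be non-negative")
  if (any(object@vDescending[!object@validNeg] != 0))
    msg <- c(msg, "vDescending must be 0 where validNeg is FALSE")
  if (any(object@vAscending[!object@validPos] != 0))
    msg <- c(msg, "vAscending must be 0 where validPos is FALSE")
  if (length(msg)) msg else TRUE
})

#' Unmixed chromophore concentration maps
#'
#' @slot hbo,hbd,icg numeric matrices, non-negative per-pixel amounts
#'   (arbitrary units) from the non-negative least-squares fit.
#' @slot residual numeric matrix, per-pixel residual 2-norm of the fit.
#' @export
setClass("ConcentrationMaps",
  representation(hbo = "matrix", hbd = "matrix", icg = "matrix",
                 residual = "matrix"))

setValidity("ConcentrationMaps", function(object) {
  if (min(object@hbo, object@hbd, object@icg) < 0)
    "concentrations must be non-negative (NNLS constraint)" else TRUE
})

#' Oxygen saturation map
#'
#' SO2 = HbO / (HbO + HbD), defined only where total hemoglobin exceeds a
#' support floor; undefined pixels carry NA and are excluded from ROI
#' statistics.
#'
#' @slot so2 numeric matrix in [0, 1] on the support, NA elsewhere.
#' @slot supportMask logical matrix.
#' @export
setClass("SO2Map",
  representation(so2 = "matrix", supportMask = "matrix"))

setValidity("SO2Map", function(object) {
  v <- object@so2[object@supportMask]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    "so2 must lie in [0, 1] on the support" else TRUE
})

## ---------------------------------------------------------------------------
## ULM
## ---------------------------------------------------------------------------

#' Set of microbubble trajectories
#'
#' @slot tracks list of data.frames with columns \code{frame}, \code{z},
#'   \code{x} (continuous pixel units) and \code{amp}; within a track the
#'   frame indices increase strictly by 1.
#' @slot framePeriod numeric(1), seconds between frames.
#' @slot pixelPitch numeric(1), mm per pixel.
#' @export
setClass("TrackSet",
  representation(tracks = "list", framePeriod = "numeric",
                 pixelPitch = "numeric"))

setValidity("TrackSet", function(object) {
  for (tr in object@tracks) {
    if (!all(c("frame", "z", "x") %in% names(tr)))
      return("each track needs columns frame, z, x")
    if (nrow(tr) > 1L && any(diff(tr$frame) != 1L))
      return("frame indices within a track must increase by exactly 1")
  }
  if (object@framePeriod <= 0) return("framePeriod must be positive")
  if (object@pixelPitch <= 0) return("pixelPitch must be positive")
  TRUE
})

#' @param tracks list of per-track data.frames (frame, z, x[, amp]).
#' @param framePeriod seconds per frame.
#' @param pixelPitch mm per pixel.
#' @return A \code{TrackSet}.
#' @rdname TrackSet-class
#' @export
trackSet <- function(tracks, framePeriod = 1.4e-3, pixelPitch = 0.1) {
  tracks <- lapply(tracks, function(tr) {
    if (is.null(tr$amp)) tr$amp <- rep(1, nrow(tr))
    tr
  })
  new("TrackSet", tracks = tracks, framePeriod = framePeriod,
      pixelPitch = pixelPitch)
}

#' Super-resolved ULM maps
#'
#' @slot density numeric matrix, microbubble count per super-resolution bin.
#' @slot directionCoded numeric matrix, density signed by track direction
#'   (+ descending, - ascending).
#' @slot meanSpeed numeric matrix, mm/s, NA where density is 0.
#' @slot gridPitch numeric(1), mm per super-resolution bin (default 0.01,
#'   i.e. a 10 um grid).
#' @export
setClass("ULMMaps",
  representation(density = "matrix", directionCoded = "matrix",
                 meanSpeed = "matrix", gridPitch = "numeric"))

setValidity("ULMMaps", function(object) {
  msg <- character()
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  if (any(!is.na(object@meanSpeed) & object@density == 0))
    msg <- c(msg, "meanSpeed defined only where density > 0")
  if (object@gridPitch <= 0) msg <- c(msg, "gridPitch must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Hemodynamic analysis
## ---------------------------------------------------------------------------

#' ROI-averaged time series
#'
#' @slot values numeric, one value per frame.
#' @slot framePeriod numeric(1), seconds per frame.
#' @slot baselineN integer(1), frames in the baseline window (default 10).
#' @slot sdValues numeric, per-frame across-pixel standard deviation (may be
#'   empty for single-trace series).
#' @export
setClass("TimeSeries",
  representation(values = "numeric", framePeriod = "numeric",
                 baselineN = "integer", sdValues = "numeric"))

setValidity("TimeSeries", function(object) {
  msg <- character()
  if (object@framePeriod <= 0) msg <- c(msg, "framePeriod must be positive")
  if (object@baselineN < 1L) msg <- c(msg, "baselineN must be >= 1")
  if (length(object@sdValues) &&
      length(object@sdValues) != length(object@values))
    msg <- c(msg, "sdValues must match values in length")
  if (length(msg)) msg else TRUE
})

#' @param values numeric vector of per-frame values.
#' @param framePeriod seconds per frame.
#' @param baselineN baseline window length in frames.
#' @param sdValues optional per-frame standard deviation.
#' @return A \code{TimeSeries}.
#' @rdname TimeSeries-class
#' @export
timeSeries <- function(values, framePeriod = 3.3, baselineN = 10L,
                       sdValues = numeric()) {
  new("TimeSeries", values = as.numeric(values), framePeriod = framePeriod,
      baselineN = as.integer(baselineN), sdValues = as.numeric(sdValues))
}

#' Relative-change (percent) time series
#'
#' Percent change of a series relative to the mean of its baseline window:
#' r(t) = 100 (x(t) - m) / m with m the mean of the first baselineN frames.
#'
#' @slot percent numeric, percent change per frame.
#' @slot baselineMean numeric(1).
#' @slot framePeriod numeric(1), seconds.
#' @slot sdPercent numeric, optional across-pixel band.
#' @export
setClass("RelativeSeries",
  representation(percent = "numeric", baselineMean = "numeric",
                 framePeriod = "numeric", sdPercent = "numeric"))

#' Stimulation paradigm
#'
#' @slot baseline,stimulusOn,post numeric(1), seconds.
#' @slot label character(1).
#' @export
setClass("StimulusParadigm",
  representation(baseline = "numeric", stimulusOn = "numeric",
                 post = "numeric", label = "character"))

setValidity("StimulusParadigm", function(object) {
  if (object@baseline <= 0 || object@stimulusOn <= 0 || object@post <= 0)
    "paradigm durations must be positive" else TRUE
})

#' @param baseline,stimulusOn,post window durations in seconds.
#' @param label paradigm label.
#' @return A \code{StimulusParadigm}; the default is the 8-min hypercapnia
#'   paradigm (2-min baseline, 3-min stimulation, 3-min post).
#' @rdname StimulusParadigm-class
#' @export
stimulusParadigm <- function(baseline = 120, stimulusOn = 180, post = 180,
                             label = "5% CO2") {
  new("StimulusParadigm", baseline = baseline, stimulusOn = stimulusOn,
      post = post, label = label)
}

#' Cross-correlation result
#'
#' @slot R numeric array: (depth, lateral, lag) for voxel-wise maps, or a
#'   1 x 1 x nLag array collapsed to a curve for ROI pairs.
#' @slot lags integer, frame offsets.
#' @slot framePeriod numeric(1), seconds, so lag seconds = lags * framePeriod.
#' @export
setClass("CrossCorrResult",
  representation(R = "array", lags = "integer", framePeriod = "numeric"))

setValidity("CrossCorrResult", function(object) {
  v <- object@R[is.finite(object@R)]
  if (length(v) && max(abs(v)) > 1 + 1e-9) "|R| must not exceed 1" else TRUE
})

## ---------------------------------------------------------------------------
## Processing configuration
## ---------------------------------------------------------------------------

#' Clutter-filter configuration
#'
#' @slot nReject integer(1), leading singular components removed (9 for the
#'   CBV path, 10 for the CBF path).
#' @slot highpassCutoff numeric(1), Hz (default 70).
#' @slot highpassOrder integer(1), Butterworth order (default 4).
#' @slot applyHighpass logical(1).
#' @export
setClass("FilterConfig",
  representation(nReject = "integer", highpassCutoff = "numeric",
                 highpassOrder = "integer", applyHighpass = "logical"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@nReject < 0L) msg <- c(msg, "nReject must be >= 0")
  if (object@highpassCutoff <= 0) msg <- c(msg, "highpassCutoff must be positive")
  if (object@highpassOrder < 1L) msg <- c(msg, "highpassOrder must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nReject leading singular components to remove.
#' @param highpassCutoff slow-time high-pass cutoff, Hz.
#' @param highpassOrder Butterworth order.
#' @param applyHighpass whether to apply the high-pass stage.
#' @return A \code{FilterConfig}.
#' @rdname FilterConfig-class
#' @export
filterConfig <- function(nReject = 9L, highpassCutoff = 70,
                         highpassOrder = 4L, applyHighpass = FALSE) {
  new("FilterConfig", nReject = as.integer(nReject),
      highpassCutoff = highpassCutoff,
      highpassOrder = as.integer(highpassOrder),
      applyHighpass = applyHighpass)
}

#' Velocimetry configuration
#'
#' Validity thresholds of the directional velocimetry chain: a directional
#' component is kept only if it holds more than the given fraction of the
#' total slow-time spectral power (0.2 positive, 0.25 negative) and its
#' normalized lag-1 autocorrelation exceeds 0.2.
#'
#' @slot posPowerFractionMin,negPowerFractionMin,autocorrMin numeric(1) in
#'   [0, 1].
#' @slot svdNReject integer(1), SVD components removed ahead of velocimetry.
#' @slot highpassCutoff numeric(1), Hz.
#' @export
setClass("VelocimetryConfig",
  representation(posPowerFractionMin = "numeric",
                 negPowerFractionMin = "numeric", autocorrMin = "numeric",
                 svdNReject = "integer", highpassCutoff = "numeric"))

setValidity("VelocimetryConfig", function(object) {
  th <- c(object@posPowerFractionMin, object@negPowerFractionMin,
          object@autocorrMin)
  if (any(th < 0) || any(th > 1)) "thresholds must lie in [0, 1]" else TRUE
})

#' @param posPowerFractionMin,negPowerFractionMin minimum power fractions.
#' @param autocorrMin minimum normalized lag-1 autocorrelation magnitude.
#' @param svdNReject SVD components removed ahead of velocimetry.
#' @param highpassCutoff high-pass cutoff, Hz.
#' @return A \code{VelocimetryConfig}.
#' @rdname VelocimetryConfig-class
#' @export
velocimetryConfig <- function(posPowerFractionMin = 0.2,
                              negPowerFractionMin = 0.25,
                              autocorrMin = 0.2, svdNReject = 10L,
                              highpassCutoff = 70) {
  new("VelocimetryConfig", posPowerFractionMin = posPowerFractionMin,
      negPowerFractionMin = negPowerFractionMin, autocorrMin = autocorrMin,
      svdNReject = as.integer(svdNReject), highpassCutoff = highpassCutoff)
}

## ---------------------------------------------------------------------------
## Dataset container
## ---------------------------------------------------------------------------

#' Dataset container binding all pipeline stages
#'
#' A single lossless container carrying the IQ movie, PA stack, named 2-D
#' output maps, simulation ground truth and provenance metadata, mirroring
#' the on-disk group layout /iq, /pa, /maps, /truth, /meta.
#'
#' @slot iq \code{IQMovie} or NULL.
#' @slot pa \code{PAStack} or NULL.
#' @slot maps named list of numeric matrices.
#' @slot truth list, simulation ground truth.
#' @slot meta list; always carries \code{version} and, when produced by a
#'   pipeline, the config snapshot and seed.
#' @export
setClass("DatasetContainer",
  representation(iq = "ANY", pa = "ANY", maps = "list", truth = "list",
                 meta = "list"))

setValidity("DatasetContainer", function(object) {
  msg <- character()
  if (!is.null(object@iq) && !is(object@iq, "IQMovie"))
    msg <- c(msg, "iq must be an IQMovie or NULL")
  if (!is.null(object@pa) && !is(object@pa, "PAStack"))
    msg <- c(msg, "pa must be a PAStack or NULL")
  if (length(object@maps) && is.null(names(object@maps)))
    msg <- c(msg, "maps must be named")
  if (length(msg)) msg else TRUE
})

#' @param iq optional \code{IQMovie}.
#' @param pa optional \code{PAStack}.
#' @param maps named list of 2-D maps.
#' @param truth simulation ground-truth list.
#' @param meta metadata list; a package version stamp is added.
#' @return A \code{DatasetContainer}.
#' @rdname DatasetContainer-class
#' @export
datasetContainer <- function(iq = NULL, pa = NULL, maps = list(),
                             truth = list(), meta = list()) {
  meta$version <- as.character(utils::packageVersion("hemofus"))
  new("DatasetContainer", iq = iq, pa = pa, maps = maps, truth = truth,
      meta = meta)
}
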