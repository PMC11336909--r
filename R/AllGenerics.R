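## Accessor generics. Slot access from user code goes through these.

#' @rdname IQMovie-class
#' @param object,x an object.
#' @export
setGeneric("iqData", function(x) standardGeneric("iqData"))
#' @rdname IQMovie-class
#' @export
setGeneric("prfc", function(x) standardGeneric("prfc"))
#' @rdname IQMovie-class
#' @export
setGeneric("centerFrequency", function(x) standardGeneric("centerFrequency"))
#' @rdname IQMovie-class
#' @export
setGeneric("soundSpeed", function(x) standardGeneric("soundSpeed"))
#' @rdname IQMovie-class
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname IQMovie-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @param x a \code{FrameSchedule}.
#' @param unit "s" or "us".
#' @export
setGeneric("framePeriod", function(x, unit = "s") standardGeneric("framePeriod"))
#' @rdname FrameSchedule-class
#' @export
setGeneric("acquisitionWindow", function(x, unit = "s") standardGeneric("acquisitionWindow"))
#' @rdname FrameSchedule-class
#' @export
setGeneric("blockDuration", function(x, unit = "s") standardGeneric("blockDuration"))
#' @rdname FrameSchedule-class
#' @export
setGeneric("scheduleEvents", function(x) standardGeneric("scheduleEvents"))

#' @rdname CBVMap-class
#' @param x a map object.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname CBVMap-class
#' @param floorDb dB floor for the log-compressed view.
#' @export
setGeneric("intensityDb", function(x, floorDb = -60) standardGeneric("intensityDb"))

#' @rdname VelocityMap-class
#' @param x a \code{VelocityMap}.
#' @export
setGeneric("vSigned", function(x) standardGeneric("vSigned"))
#' @rdname VelocityMap-class
#' @export
setGeneric("vDescending", function(x) standardGeneric("vDescending"))
#' @rdname VelocityMap-class
#' @export
setGeneric("vAscending", function(x) standardGeneric("vAscending"))
#' @rdname VelocityMap-class
#' @export
setGeneric("validityMaskPos", function(x) standardGeneric("validityMaskPos"))
#' @rdname VelocityMap-class
#' @export
setGeneric("validityMaskNeg", function(x) standardGeneric("validityMaskNeg"))

#' @rdname ConcentrationMaps-class
#' @param x a \code{ConcentrationMaps}.
#' @export
setGeneric("hbo", function(x) standardGeneric("hbo"))
#' @rdname ConcentrationMaps-class
#' @export
setGeneric("hbd", function(x) standardGeneric("hbd"))
#' @rdname ConcentrationMaps-class
#' @export
setGeneric("icg", function(x) standardGeneric("icg"))
#' @rdname ConcentrationMaps-class
#' @export
setGeneric("fitResidual", function(x) standardGeneric("fitResidual"))

#' @rdname SO2Map-class
#' @param x an \code{SO2Map}.
#' @export
setGeneric("so2", function(x) standardGeneric("so2"))
#' @rdname SO2Map-class
#' @export
setGeneric("supportMask", function(x) standardGeneric("supportMask"))

#' @rdname TrackSet-class
#' @param x a \code{TrackSet}.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
#' @rdname TrackSet-class
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname ULMMaps-class
#' @param x a \code{ULMMaps}.
#' @export
setGeneric("density_map", function(x) standardGeneric("density_map"))
#' @rdname ULMMaps-class
#' @export
setGeneric("directionCoded", function(x) standardGeneric("directionCoded"))
#' @rdname ULMMaps-class
#' @export
setGeneric("meanSpeed", function(x) standardGeneric("meanSpeed"))
#' @rdname ULMMaps-class
#' @export
setGeneric("gridPitch", function(x) standardGeneric("gridPitch"))

#' @rdname TimeSeries-class
#' @param x a series object.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname RelativeSeries-class
#' @param x a \code{RelativeSeries}.
#' @export
setGeneric("percentChange", function(x) standardGeneric("percentChange"))
#' @rdname RelativeSeries-class
#' @export
setGeneric("baselineMean", function(x) standardGeneric("baselineMean"))

#' @rdname CrossCorrResult-class
#' @param x a \code{CrossCorrResult}.
#' @export
setGeneric("corrValues", function(x) standardGeneric("corrValues"))
#' @rdname CrossCorrResult-class
#' @export
setGeneric("lagSeconds", function(x) standardGeneric("lagSeconds"))
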