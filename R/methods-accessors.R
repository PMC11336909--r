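## Accessor and show methods.

#' @rdname IQMovie-class
#' @export
setMethod("iqData", "IQMovie", function(x) x@data)
#' @rdname IQMovie-class
#' @export
setMethod("prfc", "IQMovie", function(x) x@prfc)
#' @rdname IQMovie-class
#' @export
setMethod("centerFrequency", "IQMovie", function(x) x@f0)
#' @rdname IQMovie-class
#' @export
setMethod("soundSpeed", "IQMovie", function(x) x@c)
#' @rdname IQMovie-class
#' @export
setMethod("pixelPitch", "IQMovie", function(x) x@pixelPitch)
#' @rdname TrackSet-class
#' @export
setMethod("pixelPitch", "TrackSet", function(x) x@pixelPitch)
#' @rdname IQMovie-class
#' @export
setMethod("nFrames", "IQMovie", function(x) dim(x@data)[3])

setMethod("show", "IQMovie", function(object) {
  d <- dim(object@data)
  cat("IQMovie:", d[1], "x", d[2], "px x", d[3], "frames\n")
  cat(sprintf("  f0 = %.3g MHz, c = %g m/s, PRFc = %.4g Hz, pitch = %g mm\n",
              object@f0 / 1e6, object@c, object@prfc, object@pixelPitch))
})

.us2unit <- function(us, unit) {
  unit <- match.arg(unit, c("s", "us"))
  if (unit == "s") us / 1e6 else us
}

#' @rdname FrameSchedule-class
#' @export
setMethod("framePeriod", "FrameSchedule",
          function(x, unit = "s") .us2unit(x@framePeriodUs, unit))
#' @rdname TrackSet-class
#' @export
setMethod("framePeriod", "TrackSet", function(x, unit = "s") x@framePeriod)
#' @rdname TimeSeries-class
#' @export
setMethod("framePeriod", "TimeSeries", function(x, unit = "s") x@framePeriod)
#' @rdname FrameSchedule-class
#' @export
setMethod("acquisitionWindow", "FrameSchedule",
          function(x, unit = "s") .us2unit(x@acquisitionWindowUs, unit))
#' @rdname FrameSchedule-class
#' @export
setMethod("blockDuration", "FrameSchedule",
          function(x, unit = "s") .us2unit(x@blockDurationUs, unit))
#' @rdname FrameSchedule-class
#' @export
setMethod("scheduleEvents", "FrameSchedule", function(x) x@events)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf(
    "FrameSchedule: period %g us, window %g us, block %g us, %d events\n",
    object@framePeriodUs, object@acquisitionWindowUs, object@blockDurationUs,
    nrow(object@events)))
})

#' @rdname CBVMap-class
#' @export
setMethod("intensity", "CBVMap", function(x) x@intensity)

#' @rdname CBVMap-class
#' @export
setMethod("intensityDb", "CBVMap", function(x, floorDb = -60) {
  m <- max(x@intensity)
  if (m <= 0) return(matrix(floorDb, nrow(x@intensity), ncol(x@intensity)))
  db <- 10 * log10(pmax(x@intensity / m, 10^(floorDb / 10)))
  db
})

setMethod("show", "CBVMap", function(object) {
  cat("CBVMap:", nrow(object@intensity), "x", ncol(object@intensity),
      "px, averaged over", object@nFramesUsed, "frames\n")
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@intensity), max(object@intensity)))
})

#' @rdname VelocityMap-class
#' @export
setMethod("vSigned", "VelocityMap", function(x) x@vSigned)
#' @rdname VelocityMap-class
#' @export
setMethod("vDescending", "VelocityMap", function(x) x@vDescending)
#' @rdname VelocityMap-class
#' @export
setMethod("vAscending", "VelocityMap", function(x) x@vAscending)
#' @rdname VelocityMap-class
#' @export
setMethod("validityMaskPos", "VelocityMap", function(x) x@validPos)
#' @rdname VelocityMap-class
#' @export
setMethod("validityMaskNeg", "VelocityMap", function(x) x@validNeg)

setMethod("show", "VelocityMap", function(object) {
  cat("VelocityMap:", nrow(object@vSigned), "x", ncol(object@vSigned), "px\n")
  cat(sprintf("  descending-valid %d px (max %.3g mm/s), ascending-valid %d px (max %.3g mm/s)\n",
              sum(object@validNeg), suppressWarnings(max(object@vDescending)),
              sum(object@validPos), suppressWarnings(max(object@vAscending))))
})

#' @rdname ConcentrationMaps-class
#' @export
setMethod("hbo", "ConcentrationMaps", function(x) x@hbo)
#' @rdname ConcentrationMaps-class
#' @export
setMethod("hbd", "ConcentrationMaps", function(x) x@hbd)
#' @rdname ConcentrationMaps-class
#' @export
setMethod("icg", "ConcentrationMaps", function(x) x@icg)
#' @rdname ConcentrationMaps-class
#' @export
setMethod("fitResidual", "ConcentrationMaps", function(x) x@residual)

setMethod("show", "ConcentrationMaps", function(object) {
  cat("ConcentrationMaps:", nrow(object@hbo), "x", ncol(object@hbo), "px\n")
  cat(sprintf("  max HbO %.3g, HbD %.3g, ICG %.3g; median residual %.3g\n",
              max(object@hbo), max(object@hbd), max(object@icg),
              stats::median(object@residual)))
})

#' @rdname SO2Map-class
#' @export
setMethod("so2", "SO2Map", function(x) x@so2)
#' @rdname SO2Map-class
#' @export
setMethod("supportMask", "SO2Map", function(x) x@supportMask)

setMethod("show", "SO2Map", function(object) {
  v <- object@so2[object@supportMask]
  cat("SO2Map:", nrow(object@so2), "x", ncol(object@so2), "px,",
      sum(object@supportMask), "supported\n")
  if (length(v))
    cat(sprintf("  SO2 mean %.3f (range %.3f-%.3f) on support\n",
                mean(v), min(v), max(v)))
})

#' @rdname TrackSet-class
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)
#' @rdname TrackSet-class
#' @export
setMethod("nTracks", "TrackSet", function(x) length(x@tracks))

setMethod("show", "TrackSet", function(object) {
  n <- length(object@tracks)
  len <- vapply(object@tracks, nrow, integer(1))
  cat("TrackSet:", n, "tracks,",
      if (n) sprintf("lengths %d-%d frames,", min(len), max(len)) else "",
      sprintf("frame period %.4g ms\n", object@framePeriod * 1e3))
})

#' @rdname ULMMaps-class
#' @export
setMethod("density_map", "ULMMaps", function(x) x@density)
#' @rdname ULMMaps-class
#' @export
setMethod("directionCoded", "ULMMaps", function(x) x@directionCoded)
#' @rdname ULMMaps-class
#' @export
setMethod("meanSpeed", "ULMMaps", function(x) x@meanSpeed)
#' @rdname ULMMaps-class
#' @export
setMethod("gridPitch", "ULMMaps", function(x) x@gridPitch)

setMethod("show", "ULMMaps", function(object) {
  cat("ULMMaps:", nrow(object@density), "x", ncol(object@density),
      sprintf("bins at %g um,", object@gridPitch * 1e3),
      sum(object@density), "localizations accumulated\n")
})

#' @rdname TimeSeries-class
#' @export
setMethod("seriesValues", "TimeSeries", function(x) x@values)
#' @rdname RelativeSeries-class
#' @export
setMethod("percentChange", "RelativeSeries", function(x) x@percent)
#' @rdname RelativeSeries-class
#' @export
setMethod("baselineMean", "RelativeSeries", function(x) x@baselineMean)
#' @rdname RelativeSeries-class
#' @export
setMethod("framePeriod", "RelativeSeries", function(x, unit = "s") x@framePeriod)

setMethod("show", "TimeSeries", function(object) {
  cat("TimeSeries:", length(object@values), "frames at",
      sprintf("%.4g s/frame, baseline window %d frames\n",
              object@framePeriod, object@baselineN))
})

setMethod("show", "RelativeSeries", function(object) {
  cat(sprintf(
    "RelativeSeries: %d frames, baseline mean %.4g, range [%.3g%%, %.3g%%]\n",
    length(object@percent), object@baselineMean,
    min(object@percent), max(object@percent)))
})

#' @rdname CrossCorrResult-class
#' @export
setMethod("corrValues", "CrossCorrResult", function(x) x@R)
#' @rdname CrossCorrResult-class
#' @export
setMethod("lagSeconds", "CrossCorrResult", function(x) x@lags * x@framePeriod)

setMethod("show", "CrossCorrResult", function(object) {
  d <- dim(object@R)
  cat("CrossCorrResult:", d[1], "x", d[2], "px,", d[3], "lags",
      sprintf("(%+g..%+g frames, %.3g s/frame)\n", min(object@lags),
              max(object@lags), object@framePeriod))
})

setMethod("show", "DatasetContainer", function(object) {
  cat("DatasetContainer (version", object@meta$version %||% "?", ")\n")
  cat("  /iq   :", if (is.null(object@iq)) "empty" else
    paste(dim(object@iq@data), collapse = " x "), "\n")
  cat("  /pa   :", if (is.null(object@pa)) "empty" else
    paste(dim(object@pa@images), collapse = " x "), "\n")
  cat("  /maps :", if (length(object@maps))
    paste(names(object@maps), collapse = ", ") else "empty", "\n")
  cat("  /truth:", length(object@truth), "entries\n")
})
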