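#' Accessors for the package's S4 containers
#'
#' Small accessor generics in the Bioconductor style: `framePixels()`,
#' `frameScale()`, `mmPerPixel()`, `sourceId()` for frames; `roiMask()` and
#' `pixelCount()` for regions; `meanPI()` and `piHistogram()` for
#' echodensity results; `traceTime()`, `tracePosition()`, `sampleRate()` for
#' traces; `perBreathAmplitudes()`, `meanAmplitude()`, `nBreathsUsed()` for
#' amplitude results; `awRecords()`, `attenuationR()`, `attenuationR2()`,
#' `nColumns()`, `nPixelsAnalyzed()` for attenuation datasets.
#'
#' @param x the object.
#' @return The slot value (see the class documentation for units).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))
#' @rdname accessors
#' @export
setGeneric("frameScale", function(x) standardGeneric("frameScale"))
#' @rdname accessors
#' @export
setGeneric("mmPerPixel", function(x) standardGeneric("mmPerPixel"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))
#' @rdname accessors
#' @export
setGeneric("meanPI", function(x) standardGeneric("meanPI"))
#' @rdname accessors
#' @export
setGeneric("piHistogram", function(x) standardGeneric("piHistogram"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("tracePosition", function(x) standardGeneric("tracePosition"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("perBreathAmplitudes", function(x) standardGeneric("perBreathAmplitudes"))
#' @rdname accessors
#' @export
setGeneric("meanAmplitude", function(x) standardGeneric("meanAmplitude"))
#' @rdname accessors
#' @export
setGeneric("nBreathsUsed", function(x) standardGeneric("nBreathsUsed"))
#' @rdname accessors
#' @export
setGeneric("awRecords", function(x) standardGeneric("awRecords"))
#' @rdname accessors
#' @export
setGeneric("attenuationR", function(x) standardGeneric("attenuationR"))
#' @rdname accessors
#' @export
setGeneric("attenuationR2", function(x) standardGeneric("attenuationR2"))
#' @rdname accessors
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))
#' @rdname accessors
#' @export
setGeneric("nPixelsAnalyzed", function(x) standardGeneric("nPixelsAnalyzed"))
#' @rdname accessors
#' @export
setGeneric("crossSectionalArea", function(x) standardGeneric("crossSectionalArea"))

#' @rdname accessors
setMethod("framePixels", "UltrasoundFrame", function(x) x@pixels)
#' @rdname accessors
setMethod("frameScale", "UltrasoundFrame", function(x) x@scale)
#' @rdname accessors
setMethod("mmPerPixel", "UltrasoundFrame", function(x) x@mmPerPixel)
#' @rdname accessors
setMethod("sourceId", "UltrasoundFrame", function(x) x@sourceId)
#' @rdname accessors
setMethod("roiMask", "ROI", function(x) x@mask)
#' @rdname accessors
setMethod("pixelCount", "ROI", function(x) sum(x@mask))
#' @rdname accessors
setMethod("pixelCount", "EchodensityResult", function(x) x@pixelCount)
#' @rdname accessors
setMethod("meanPI", "EchodensityResult", function(x) x@meanPI)
#' @rdname accessors
setMethod("piHistogram", "EchodensityResult", function(x) x@histogram)
#' @rdname accessors
setMethod("traceTime", "MModeTrace", function(x) x@time)
#' @rdname accessors
setMethod("tracePosition", "MModeTrace", function(x) x@position)
#' @rdname accessors
setMethod("sampleRate", "MModeTrace", function(x) x@sampleRate)
#' @rdname accessors
setMethod("perBreathAmplitudes", "AmplitudeResult", function(x) x@perBreath)
#' @rdname accessors
setMethod("meanAmplitude", "AmplitudeResult", function(x) x@meanAmplitude)
#' @rdname accessors
setMethod("nBreathsUsed", "AmplitudeResult", function(x) x@nUsed)
#' @rdname accessors
setMethod("awRecords", "AttenuationDataset", function(x) x@records)
#' @rdname accessors
setMethod("attenuationR", "AttenuationDataset", function(x) x@r)
#' @rdname accessors
setMethod("attenuationR2", "AttenuationDataset", function(x) x@rSquared)
#' @rdname accessors
setMethod("nColumns", "AttenuationDataset", function(x) x@nColumns)
#' @rdname accessors
setMethod("nPixelsAnalyzed", "AttenuationDataset", function(x) x@nPixelsAnalyzed)

setMethod("dim", "UltrasoundFrame", function(x) dim(x@pixels))

setMethod("show", "UltrasoundFrame", function(object) {
  cat(sprintf(
    "UltrasoundFrame %dx%d [%s]%s%s\n",
    nrow(object@pixels), ncol(object@pixels), object@scale,
    if (is.na(object@mmPerPixel)) "" else sprintf(" %.4g mm/px", object@mmPerPixel),
    if (nzchar(object@sourceId)) paste0(" <", object@sourceId, ">") else ""
  ))
  cat(sprintf(
    "  intensity range: [%.4g, %.4g]\n",
    min(object@pixels), max(object@pixels)
  ))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf(
    "ROI %dx%d, %d pixels inside\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask)
  ))
})

setMethod("show", "EchodensityResult", function(object) {
  cat(sprintf(
    "EchodensityResult: mean P.I. %.2f over %d pixels (%d frame%s)\n",
    object@meanPI, object@pixelCount, length(object@frameIds),
    if (length(object@frameIds) == 1L) "" else "s"
  ))
})

setMethod("show", "MModeTrace", function(object) {
  cat(sprintf(
    "MModeTrace: %d samples @ %.4g Hz, %.3g s, position range [%.3g, %.3g] mm\n",
    length(object@time), object@sampleRate,
    object@time[length(object@time)] - object@time[1],
    min(object@position), max(object@position)
  ))
})

setMethod("show", "AmplitudeResult", function(object) {
  cat(sprintf(
    "AmplitudeResult: mean amplitude %.3f mm over %d breath%s (%s)\n",
    object@meanAmplitude, object@nUsed, if (object@nUsed == 1L) "" else "s",
    paste(sprintf("%.3f", object@perBreath), collapse = ", ")
  ))
})

setMethod("show", "AttenuationDataset", function(object) {
  cat(sprintf(
    "AttenuationDataset: %d columns, %d pixels analyzed\n",
    object@nColumns, object@nPixelsAnalyzed
  ))
  cat(sprintf(
    "  ratio ~ thickness: r = %.4f, R^2 = %.5f (slope %.3g, intercept %.3g)\n",
    object@r, object@rSquared, object@slope, object@intercept
  ))
  if (nrow(object@perImage) > 0L) {
    cat(sprintf("  images: %d\n", nrow(object@perImage)))
  }
})

setMethod("show", "MusclePrep", function(object) {
  cat(sprintf(
    "MusclePrep: mass %.4g g, L0 %.4g cm, Lf/L0 %.3g, density %.3g g/cm^3 -> CSA %.4g cm^2\n",
    object@mass, object@l0, object@lengthToFiberRatio, object@density,
    crossSectionalArea(object)
  ))
})
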