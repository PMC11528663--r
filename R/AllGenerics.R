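#' @rdname FrameSeries-class
#' @param object,x a \linkS4class{FrameSeries} (or other myxometry object).
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSeries-class
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname FrameSeries-class
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname FrameSeries-class
#' @param value replacement value.
#' @export
setGeneric("pixelPitch<-", function(x, value) standardGeneric("pixelPitch<-"))

#' @rdname FrameSeries-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname VeinSectionSet-class
#' @export
setGeneric("sections", function(x) standardGeneric("sections"))

#' @rdname VeinSectionSet-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname VeinSectionSet-class
#' @export
setGeneric("activeSections", function(x) standardGeneric("activeSections"))

#' @rdname SpectralEstimate-class
#' @export
setGeneric("estFrequency", function(x) standardGeneric("estFrequency"))

#' @export
#' @rdname FrameSeries-class
setMethod("frames", "FrameSeries", function(x) x@frames)

#' @export
#' @rdname FrameSeries-class
setMethod("timestamps", "FrameSeries", function(x) x@timestamps)

#' @export
#' @rdname FrameSeries-class
setMethod("pixelPitch", "FrameSeries", function(x) x@pixelPitch)

#' @export
#' @rdname FrameSeries-class
setMethod("pixelPitch", "ScaleCalibration", function(x) x@pixelPitch)

#' @export
#' @rdname FrameSeries-class
setReplaceMethod("pixelPitch", "FrameSeries", function(x, value) {
  x@pixelPitch <- as.numeric(value)
  validObject(x)
  x
})

#' @export
#' @rdname FrameSeries-class
setMethod("nFrames", "FrameSeries", function(x) length(x@frames))

#' @export
#' @rdname FrameSeries-class
#' @param i frame index.
setMethod("[[", "FrameSeries", function(x, i) x@frames[[i]])

#' @export
#' @rdname VeinSectionSet-class
setMethod("sections", "VeinSectionSet", function(x) x@sections)

#' @export
#' @rdname VeinSectionSet-class
setMethod("positions", "VeinSectionSet", function(x) x@positions)

#' @export
#' @rdname VeinSectionSet-class
setMethod("activeSections", "VeinSectionSet", function(x)
  x@sections$section_id[x@sections$status == "active"])

#' @export
#' @rdname SpectralEstimate-class
setMethod("estFrequency", "SpectralEstimate", function(x) x@estFrequencyHz)

setMethod("show", "FrameSeries", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf(
    "FrameSeries: %d frames of %d x %d px, %.1f s span, pitch %s um/px\n",
    length(object@frames), d[1], d[2], diff(range(object@timestamps)),
    if (is.na(object@pixelPitch)) "uncalibrated"
    else format(object@pixelPitch, digits = 4)))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: centre (%.1f, %.1f), radius %.1f px, %d px inside\n",
              object@center[1], object@center[2], object@radius,
              sum(object@mask)))
})

setMethod("show", "AreaSeries", function(object) {
  cat(sprintf(
    "AreaSeries [%s]: %d timepoints over %.2f h, area %.3f -> %.3f mm^2\n",
    object@condition, length(object@timesH), max(object@timesH),
    object@areaMm2[1], object@areaMm2[length(object@areaMm2)]))
})

setMethod("show", "ExplorationSeries", function(object) {
  cat(sprintf(
    "ExplorationSeries: %d timepoints, explored %.3f mm^2 at %.2f h\n",
    length(object@timesH), object@exploredMm2[length(object@exploredMm2)],
    max(object@timesH)))
})

setMethod("show", "FractalSeries", function(object) {
  cat(sprintf(
    "FractalSeries: %d timepoints, D in [%.3f, %.3f], %d box sizes\n",
    length(object@timesH), min(object@dimension), max(object@dimension),
    length(object@boxSizes)))
})

setMethod("show", "VeinSectionSet", function(object) {
  n <- nrow(object@sections)
  act <- sum(object@sections$status == "active")
  cat(sprintf("VeinSectionSet: %d sections (%d active, %d rejected)\n",
              n, act, n - act))
  if (n - act > 0) {
    tab <- table(object@sections$reject_reason[
      object@sections$status == "rejected"])
    cat("  rejections:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf(
    "SpectralEstimate [%s]: %.4f Hz (%.2f mHz) over %d slices%s\n",
    object@sectionId, object@estFrequencyHz, 1000 * object@estFrequencyHz,
    length(object@sliceFreqs),
    if (isTRUE(object@lowConfidence)) " [low confidence]" else ""))
})

setMethod("show", "DiameterDistribution", function(object) {
  cat(sprintf(
    "DiameterDistribution: %d intervals, step %.2f um, range [%.1f, %.1f] um\n",
    object@nIntervals, object@stepsize, min(object@edges), max(object@edges)))
})

setMethod("show", "VolumeEstimate", function(object) {
  cat(sprintf(
    "VolumeEstimate: %.4f mm^3 over %.2f mm^2 (normalised %.4f mm)\n",
    object@totalMm3, object@areaMm2, object@normalizedMm))
  if (length(object@errorRange))
    cat(sprintf("  worst-case volume interval: [%.4f, %.4f] mm^3\n",
                object@errorRange$volume_interval[1],
                object@errorRange$volume_interval[2]))
})
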