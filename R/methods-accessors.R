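#' @rdname IMURecording-class
#' @aliases subjectId samplingRate accel gyro groundTruth
setMethod("subjectId", "IMURecording", function(object) object@subjectId)

#' @rdname IMURecording-class
setMethod("samplingRate", "IMURecording", function(object) object@samplingRate)

#' @rdname IMURecording-class
setMethod("accel", "IMURecording", function(object) object@accel)

#' @rdname IMURecording-class
setMethod("gyro", "IMURecording", function(object) object@gyro)

#' @rdname IMURecording-class
setMethod("groundTruth", "IMURecording", function(object) object@groundTruth)

#' @rdname IMURecording-class
#' @export
setMethod("length", "IMURecording", function(x) length(x@time))

#' @export
setMethod("show", "IMURecording", function(object) {
  cat("IMURecording '", object@subjectId, "': ", length(object@time),
      " samples at ", object@samplingRate, " Hz (",
      sprintf("%.1f", length(object@time) / object@samplingRate / 60),
      " min)", if (length(object@groundTruth)) ", with ground truth" else "",
      "\n", sep = "")
})

#' @rdname ActivityAnnotation-class
setMethod("keepMask", "ActivityAnnotation", function(object) object@keepMask)

#' @rdname ActivityAnnotation-class
setMethod("activeSegments", "ActivityAnnotation", function(object) object@segments)

#' @rdname ActivityAnnotation-class
setMethod("totalActiveS", "ActivityAnnotation", function(object) {
  sum(object@keepMask & object@wearMask) / object@samplingRate
})

#' @rdname ActivityAnnotation-class
setMethod("totalInactiveS", "ActivityAnnotation", function(object) {
  sum(!object@keepMask & object@wearMask) / object@samplingRate
})

#' @rdname ActivityAnnotation-class
setMethod("inactiveFraction", "ActivityAnnotation", function(object) {
  wear <- sum(object@wearMask)
  if (wear == 0) return(NA_real_)
  sum(!object@keepMask & object@wearMask) / wear
})

#' @export
setMethod("show", "ActivityAnnotation", function(object) {
  cat("ActivityAnnotation: ", length(object@u), " samples, ",
      nrow(object@segments), " active segments, inactive fraction ",
      sprintf("%.3f", inactiveFraction(object)), "\n", sep = "")
})

#' @rdname TiltSeries-class
setMethod("tiltDegrees", "TiltSeries", function(object) object@theta)

#' @rdname TiltSeries-class
setMethod("validMask", "TiltSeries", function(object) object@valid)

#' @rdname TiltSeries-class
#' @export
setMethod("length", "TiltSeries", function(x) length(x@theta))

#' @export
setMethod("show", "TiltSeries", function(object) {
  cat("TiltSeries: ", length(object@theta), " samples, ",
      sum(object@valid), " valid\n", sep = "")
})

#' @rdname SampEnResult-class
setMethod("subjectValue", "SampEnResult", function(object) object@subjectValue)

#' @export
setMethod("show", "SampEnResult", function(object) {
  cat("SampEnResult: ", object@nSegmentsUsed, " windows used, ",
      object@nSegmentsUndefined, " undefined; subject value ",
      sprintf("%.4f", object@subjectValue), " nats\n", sep = "")
})

#' @rdname QOMEExperiment-class
setMethod("uefm", "QOMEExperiment", function(object) {
  SummarizedExperiment::colData(object)$uefm
})

#' @rdname QOMEExperiment-class
setMethod("featureMatrix", "QOMEExperiment", function(object) {
  SummarizedExperiment::assay(object, "features")
})
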