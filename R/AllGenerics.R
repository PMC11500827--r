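#' @rdname IMURecording-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname IMURecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname IMURecording-class
#' @export
setGeneric("accel", function(object) standardGeneric("accel"))

#' @rdname IMURecording-class
#' @export
setGeneric("gyro", function(object) standardGeneric("gyro"))

#' @rdname IMURecording-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname ActivityAnnotation-class
#' @export
setGeneric("keepMask", function(object) standardGeneric("keepMask"))

#' @rdname ActivityAnnotation-class
#' @export
setGeneric("activeSegments", function(object) standardGeneric("activeSegments"))

#' @rdname ActivityAnnotation-class
#' @export
setGeneric("totalActiveS", function(object) standardGeneric("totalActiveS"))

#' @rdname ActivityAnnotation-class
#' @export
setGeneric("totalInactiveS", function(object) standardGeneric("totalInactiveS"))

#' @rdname ActivityAnnotation-class
#' @export
setGeneric("inactiveFraction", function(object) standardGeneric("inactiveFraction"))

#' @rdname TiltSeries-class
#' @export
setGeneric("tiltDegrees", function(object) standardGeneric("tiltDegrees"))

#' @rdname TiltSeries-class
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname SampEnResult-class
#' @export
setGeneric("subjectValue", function(object) standardGeneric("subjectValue"))

#' @rdname QOMEExperiment-class
#' @export
setGeneric("uefm", function(object) standardGeneric("uefm"))

#' @rdname QOMEExperiment-class
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
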