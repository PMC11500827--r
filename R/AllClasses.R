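#' @import methods
#' @importFrom stats approx coef cor cor.test dist lm logLik pbeta plogis
#'   pnorm pt qbeta qnorm rbinom rgamma rlnorm rnorm runif sd t.test var aov
#' @importFrom utils read.csv write.csv
#' @useDynLib wristqome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' Subject profile for the synthetic cohort generator
#'
#' A `SubjectProfile` holds the latent parameters that control the
#' statistical structure of one synthetic wrist-IMU recording: how much of
#' the day the arm is active, how concentrated the forearm tilt-angle
#' distribution is, how complex (broadband vs. oscillatory) the tilt
#' trajectory is, and how fast movements are. The clinical anchor is the
#' Upper Extremity Fugl-Meyer (UEFM) score (0-66, higher = less impaired).
#'
#' @slot subjectId character identifier.
#' @slot uefm numeric UEFM score in `[0, 66]`.
#' @slot activeFraction fraction of wear time spent in movement bouts,
#'   in `[0, 1)`.
#' @slot tiltConcentration unitless concentration of the tilt-angle
#'   distribution in `[0, 1)`; realized as the mixture weight of a narrow
#'   "postural stagnation" peak at the modal tilt, so higher values give a
#'   narrower, more peaked (leptokurtic) distribution.
#' @slot complexityLevel mixing weight in `[0, 1]` between a predictable
#'   0.5 Hz oscillatory tilt process (0) and a broadband stochastic AR(1)
#'   process (1).
#' @slot speedScale multiplier on movement linear-acceleration magnitudes.
#' @slot modeDeg modal tilt angle in degrees (default 95).
#' @slot tiltScale per-subject affine scale of tilt excursions about the
#'   mode (nuisance variation; changes variance, not kurtosis).
#' @slot gyroNoiseScale per-subject multiplier on gyroscope sensor noise.
#' @slot seed integer RNG seed; identical profiles reproduce identical
#'   recordings bit for bit.
#' @export
setClass("SubjectProfile",
  representation(
    subjectId = "character",
    uefm = "numeric",
    activeFraction = "numeric",
    tiltConcentration = "numeric",
    complexityLevel = "numeric",
    speedScale = "numeric",
    modeDeg = "numeric",
    tiltScale = "numeric",
    gyroNoiseScale = "numeric",
    seed = "integer"
  )
)

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (length(object@uefm) != 1 || object@uefm < 0 || object@uefm > 66)
    msg <- c(msg, "uefm must be a single score in [0, 66]")
  if (object@activeFraction < 0 || object@activeFraction >= 1)
    msg <- c(msg, "activeFraction must be in [0, 1)")
  if (object@tiltConcentration < 0 || object@tiltConcentration >= 1)
    msg <- c(msg, "tiltConcentration must be in [0, 1)")
  if (object@complexityLevel < 0 || object@complexityLevel > 1)
    msg <- c(msg, "complexityLevel must be in [0, 1]")
  if (object@speedScale <= 0) msg <- c(msg, "speedScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Raw wrist-IMU recording
#'
#' Triaxial accelerometer (gravity-inclusive, m/s^2) and gyroscope (deg/s)
#' time series for one subject, sampled at a fixed rate (52.6 Hz for the
#' device emulated here). The sensor frame follows the pronated-horizontal
#' convention: +X posterior, +Y medial, +Z vertical. Synthetic recordings
#' carry their generative ground truth (latent tilt trajectory and active
#' bout mask) in `groundTruth`.
#'
#' @slot subjectId character identifier.
#' @slot samplingRate sampling rate in Hz.
#' @slot time timestamps in seconds, strictly increasing, uniform spacing.
#' @slot accel n x 3 matrix, m/s^2, gravity-inclusive.
#' @slot gyro n x 3 matrix, deg/s.
#' @slot groundTruth list; for synthetic recordings, `tilt` (deg) and
#'   `active` (logical) per sample. Empty for real data.
#' @export
setClass("IMURecording",
  representation(
    subjectId = "character",
    samplingRate = "numeric",
    time = "numeric",
    accel = "matrix",
    gyro = "matrix",
    groundTruth = "list"
  ),
  prototype(groundTruth = list())
)

setValidity("IMURecording", function(object) {
  n <- length(object@time)
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (nrow(object@accel) != n || nrow(object@gyro) != n)
    msg <- c(msg, "accel, gyro and time must have equal length")
  if (ncol(object@accel) != 3 || ncol(object@gyro) != 3)
    msg <- c(msg, "accel and gyro must have 3 columns")
  if (!all(is.finite(object@time)) || !all(is.finite(object@accel)) ||
      !all(is.finite(object@gyro)))
    msg <- c(msg, "all values must be finite")
  if (n > 1) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    if (max(abs(dt - 1 / object@samplingRate)) > 1e-6)
      msg <- c(msg, "timestamp spacing must equal 1/samplingRate")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample arm-activity annotation
#'
#' Output of the two-threshold inactivity filter: the binary instantaneous
#' use score u (1 where the gravity-subtracted acceleration magnitude
#' exceeds a threshold in G), its trailing windowed mean U, the keep mask
#' (active where U is at or above the fraction threshold), and the maximal
#' runs of kept samples as half-open index segments.
#'
#' @slot u integer 0/1 per sample.
#' @slot U numeric in `[0, 1]` per sample; trailing mean of `u`.
#' @slot keepMask logical per sample; `TRUE` = active.
#' @slot segments integer matrix with columns `start`, `end` (half-open,
#'   1-based: samples `start .. end - 1` are kept).
#' @slot samplingRate Hz.
#' @slot config the `filterConfig()` list used.
#' @slot wearMask logical per sample; `FALSE` where samples were excluded
#'   from wear time (constant-signal dropout).
#' @export
setClass("ActivityAnnotation",
  representation(
    u = "integer",
    U = "numeric",
    keepMask = "logical",
    segments = "matrix",
    samplingRate = "numeric",
    config = "list",
    wearMask = "logical"
  )
)

setValidity("ActivityAnnotation", function(object) {
  msg <- character()
  n <- length(object@u)
  if (length(object@U) != n || length(object@keepMask) != n ||
      length(object@wearMask) != n)
    msg <- c(msg, "u, U, keepMask and wearMask must have equal length")
  if (any(object@U < -1e-12 | object@U > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "U must lie in [0, 1]")
  if (nrow(object@segments) > 0) {
    covered <- logical(n)
    for (i in seq_len(nrow(object@segments))) {
      covered[object@segments[i, 1]:(object@segments[i, 2] - 1)] <- TRUE
    }
    if (!identical(covered, object@keepMask & object@wearMask))
      msg <- c(msg, "segments must partition exactly the kept wear samples")
  }
  if (length(msg)) msg else TRUE
})

#' Forearm tilt-angle series
#'
#' Per-sample tilt angle Theta in degrees in `[0, 180]`: the angle between
#' the world vertical and the projection of the measured (gravity-dominant)
#' acceleration vector, Theta = arccos(-a_z / ||a||). Samples where the
#' acceleration magnitude falls below a floor are flagged invalid rather
#' than raised.
#'
#' @slot theta numeric, degrees in `[0, 180]` where valid.
#' @slot valid logical per sample.
#' @export
setClass("TiltSeries",
  representation(theta = "numeric", valid = "logical")
)

setValidity("TiltSeries", function(object) {
  msg <- character()
  if (length(object@theta) != length(object@valid))
    msg <- c(msg, "theta and valid must have equal length")
  th <- object@theta[object@valid]
  if (length(th) && any(th < -1e-9 | th > 180 + 1e-9))
    msg <- c(msg, "valid tilt angles must lie in [0, 180] degrees")
  if (length(msg)) msg else TRUE
})

#' Windowed Sample Entropy result
#'
#' Per-window Sample Entropy values (nats) for one signal of one recording,
#' plus the subject-level aggregate (mean over windows where the entropy is
#' defined, i.e. where at least one template match of each length existed).
#'
#' @slot values numeric per-window entropies; `NA` where undefined.
#' @slot subjectValue mean of the defined window entropies (`NA` if none).
#' @slot nSegmentsUsed number of windows with a defined entropy.
#' @slot nSegmentsUndefined number of windows with undefined entropy.
#' @slot params the `sampEnParams()` list used.
#' @export
setClass("SampEnResult",
  representation(
    values = "numeric",
    subjectValue = "numeric",
    nSegmentsUsed = "integer",
    nSegmentsUndefined = "integer",
    params = "list"
  )
)

setValidity("SampEnResult", function(object) {
  defined <- object@values[!is.na(object@values)]
  msg <- character()
  if (length(defined) && any(defined < -1e-12))
    msg <- c(msg, "defined entropies must be non-negative")
  if (length(defined) != object@nSegmentsUsed)
    msg <- c(msg, "nSegmentsUsed must count the defined windows")
  if (length(msg)) msg else TRUE
})

#' Cohort feature container
#'
#' A `SummarizedExperiment` whose assay `features` holds the per-recording
#' movement-experience quality feature matrix (features x subjects) and
#' whose `colData` carries the clinical metadata (`uefm`, optionally `bbt`
#' and the impairment `group`).
#'
#' @export
setClass("QOMEExperiment", contains = "SummarizedExperiment")

setValidity("QOMEExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!"uefm" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'uefm' column")
  } else if (any(cd$uefm < 0 | cd$uefm > 66, na.rm = TRUE)) {
    msg <- c(msg, "uefm scores must lie in [0, 66]")
  }
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (length(msg)) msg else TRUE
})
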