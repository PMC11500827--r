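# Forearm tilt angle with respect to gravity.

#' Tilt angle from raw acceleration
#'
#' Computes the forearm tilt angle Theta = arccos(-a_z / ||a||) in degrees
#' from the raw, gravity-inclusive acceleration: the angle between the
#' world vertical and the measured acceleration direction, 0 degrees when
#' the sensor reads (0, 0, -g) and 180 degrees at (0, 0, +g). The formula
#' projects the gravity vector, so it must be applied to the raw signal,
#' not the gravity-subtracted one. Samples whose acceleration magnitude
#' falls below `magnitudeFloor` are flagged invalid rather than raised.
#'
#' @param x an [IMURecording-class] or an n x 3 acceleration matrix
#'   (m/s^2, gravity-inclusive).
#' @param magnitudeFloor minimum ||a|| (m/s^2) for a valid angle;
#'   default 0.5.
#' @return a [TiltSeries-class].
#' @examples
#' tiltDegrees(tiltAngle(rbind(c(0, 0, -9.81), c(9.81, 0, 0), c(0, 0, 9.81))))
#' @export
tiltAngle <- function(x, magnitudeFloor = 0.5) {
  a <- if (is(x, "IMURecording")) x@accel else as.matrix(x)
  stopifnot(ncol(a) == 3)
  mag <- sqrt(rowSums(a^2))
  valid <- mag >= magnitudeFloor
  theta <- rep(NA_real_, nrow(a))
  ratio <- pmin(pmax(-a[valid, 3] / mag[valid], -1), 1)
  theta[valid] <- acos(ratio) * 180 / pi
  new("TiltSeries", theta = theta, valid = valid)
}

#' Tilt angle over active time
#'
#' Computes the tilt angle on the raw acceleration and restricts validity
#' to the samples kept by the activity filter (and inside wear time).
#' An optional boxcar smoother of the tilt series is provided; the default
#' applies none.
#'
#' @param rec an [IMURecording-class].
#' @param ann an [ActivityAnnotation-class] aligned with `rec`.
#' @param magnitudeFloor minimum ||a|| for a valid angle, m/s^2.
#' @param smoothS optional boxcar length in seconds (0 = no smoothing).
#' @return a [TiltSeries-class] whose `valid` mask is the conjunction of
#'   angle validity, the keep mask and the wear mask.
#' @export
tiltForActive <- function(rec, ann, magnitudeFloor = 0.5, smoothS = 0) {
  stopifnot(is(rec, "IMURecording"), is(ann, "ActivityAnnotation"))
  if (length(rec@time) != length(ann@u))
    stop("annotation length does not match the recording")
  ts <- tiltAngle(rec@accel, magnitudeFloor)
  if (smoothS > 0) {
    k <- max(round(smoothS * rec@samplingRate), 1L)
    if (k %% 2 == 0) k <- k + 1L
    sm <- as.numeric(stats::filter(ts@theta, rep(1 / k, k), sides = 2))
    ok <- !is.na(sm)
    ts@theta[ok] <- sm[ok]
  }
  ts@valid <- ts@valid & ann@keepMask & ann@wearMask
  ts
}
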