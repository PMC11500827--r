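# Distributional movement-experience quality features.

#' Binned magnitude distribution
#'
#' Histograms active-time magnitudes on the fixed clinical grids:
#' acceleration in 30 half-open bins of 1 m/s^2 over `[0, 30)`, angular
#' velocity in 20 half-open bins of 5 deg/s over `[0, 100)`. Observations
#' at or beyond the upper range are counted separately (`nOutOfRange`) and
#' excluded from the normalization.
#'
#' @param x numeric vector of non-negative magnitudes (active samples).
#' @param kind `"accel"` (m/s^2) or `"gyro"` (deg/s).
#' @return list of class `MagnitudeHistogram`: `edges`, `counts`,
#'   `normalized`, `nOutOfRange`, `kind`.
#' @export
magnitudeHistogram <- function(x, kind = c("accel", "gyro")) {
  kind <- match.arg(kind)
  if (!length(x)) stop("empty input")
  edges <- if (kind == "accel") seq(0, 30, by = 1) else seq(0, 100, by = 5)
  idx <- findInterval(x, edges, left.open = FALSE, rightmost.closed = FALSE)
  inRange <- idx >= 1 & idx <= length(edges) - 1
  counts <- tabulate(idx[inRange], nbins = length(edges) - 1)
  total <- sum(counts)
  structure(list(edges = edges, counts = counts,
                 normalized = if (total > 0) counts / total else counts,
                 nOutOfRange = sum(!inRange), kind = kind),
            class = "MagnitudeHistogram")
}

# sum of counts over [lo, hi) given unit-spaced half-open bins
.binMass <- function(hist, lo, hi) {
  sel <- hist$edges[-length(hist$edges)] >= lo & hist$edges[-1] <= hi
  sum(hist$counts[sel])
}

#' Acceleration speed ratio
#'
#' Ratio of the number of active-time acceleration-magnitude observations
#' in `[1, 3)` m/s^2 to the number in `[0, 1)` m/s^2: the relative time
#' spent moving at higher speed. Returns `+Inf` (flagged by callers and
#' excluded from cohort statistics) when the denominator is zero.
#'
#' @param hist an acceleration `MagnitudeHistogram`.
#' @return the ratio (unitless).
#' @export
accelRatio <- function(hist) {
  stopifnot(inherits(hist, "MagnitudeHistogram"), hist$kind == "accel")
  den <- .binMass(hist, 0, 1)
  num <- .binMass(hist, 1, 3)
  if (den == 0) return(Inf)
  num / den
}

#' Angular-velocity speed ratio
#'
#' By default the ratio of observations in `[5, 15)` deg/s to observations
#' in `[0, 5)` deg/s, the high/low orientation consistent with
#' [accelRatio()]. `literal = TRUE` gives the reciprocal (low/high)
#' reading.
#'
#' @param hist a gyro `MagnitudeHistogram`.
#' @param literal use the low/high orientation instead.
#' @return the ratio (unitless); `+Inf` when the denominator is zero.
#' @export
gyroRatio <- function(hist, literal = FALSE) {
  stopifnot(inherits(hist, "MagnitudeHistogram"), hist$kind == "gyro")
  slow <- .binMass(hist, 0, 5)
  fast <- .binMass(hist, 5, 15)
  num <- if (literal) slow else fast
  den <- if (literal) fast else slow
  if (den == 0) return(Inf)
  num / den
}

#' Moments of the tilt-angle distribution
#'
#' Sample skewness (g1), excess kurtosis (g2 = m4/m2^2 - 3) and variance of
#' the valid tilt samples, using population-moment definitions (no
#' small-sample bias correction; recordings contribute thousands of
#' samples). Excess kurtosis near 0 indicates a near-normal posture
#' distribution; large positive values indicate postural stagnation
#' (a narrow peak with occasional excursions).
#'
#' @param tilt a [TiltSeries-class] or numeric vector of angles (deg).
#' @return named numeric: `kurtosis` (excess), `skewness`, `variance`
#'   (deg^2).
#' @export
tiltMoments <- function(tilt) {
  th <- if (is(tilt, "TiltSeries")) tilt@theta[tilt@valid] else as.numeric(tilt)
  th <- th[!is.na(th)]
  if (length(th) < 4) stop("need at least 4 valid tilt samples")
  m <- mean(th)
  d <- th - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("tilt distribution is degenerate (zero variance)")
  c(kurtosis = mean(d^4) / m2^2 - 3,
    skewness = mean(d^3) / m2^1.5,
    variance = m2)
}

#' Mean movement magnitudes
#'
#' Arithmetic means of the active-time acceleration magnitude (m/s^2) and
#' angular-velocity magnitude (deg/s).
#'
#' @param accelMag,gyroMag numeric vectors of active-sample magnitudes.
#' @return named numeric `accel_mean`, `gyro_mean`.
#' @export
magnitudeMeans <- function(accelMag, gyroMag) {
  if (!length(accelMag) || !length(gyroMag)) stop("empty input")
  c(accel_mean = mean(accelMag), gyro_mean = mean(gyroMag))
}

#' Normalized tilt-angle distribution
#'
#' 91 equal-width bins over `[0, 180]` degrees (edges
#' `seq(0, 180, length.out = 92)`, ~2 degrees per bin), normalized to
#' proportions.
#'
#' @param tilt a [TiltSeries-class] or numeric vector of angles (deg).
#' @return list `edges`, `counts`, `normalized`.
#' @export
tiltHistogram <- function(tilt) {
  th <- if (is(tilt, "TiltSeries")) tilt@theta[tilt@valid] else as.numeric(tilt)
  th <- th[!is.na(th)]
  if (!length(th)) stop("empty input")
  edges <- seq(0, 180, length.out = 92)
  idx <- findInterval(th, edges, rightmost.closed = TRUE)
  idx[idx == 92] <- 91   # close the last bin
  counts <- tabulate(idx, nbins = 91)
  list(edges = edges, counts = counts, normalized = counts / sum(counts))
}

#' Movement-experience quality features for one recording
#'
#' Runs the full per-recording pipeline: Madgwick gravity removal,
#' constant-signal dropout removal, the two-threshold activity filter,
#' tilt-angle estimation over active time, then the ten distributional and
#' complexity features plus the inactive fraction.
#'
#' @param rec an [IMURecording-class].
#' @param config a [filterConfig()].
#' @param beta Madgwick gain for gravity removal.
#' @param literalGyroRatio see [gyroRatio()].
#' @return named numeric vector with elements `tilt_kurtosis`,
#'   `tilt_skewness`, `tilt_variance`, `accel_ratio`, `gyro_ratio`,
#'   `accel_mean`, `gyro_mean`, `sampen_accel`, `sampen_gyro`,
#'   `sampen_tilt`, `inactive_fraction`; histograms are attached as
#'   attributes `accelHist`, `gyroHist`, `tiltHist`.
#' @export
recordingFeatures <- function(rec, config = filterConfig(), beta = 0.1,
                              literalGyroRatio = FALSE) {
  stopifnot(is(rec, "IMURecording"))
  lin <- removeGravity(rec, beta = beta)
  wear <- dropConstantPeriods(rec, config$dropoutMinS, config$constantTol)
  ann <- activityFilter(lin, rec@samplingRate, config, wearMask = wear)
  tilt <- tiltForActive(rec, ann)
  keep <- ann@keepMask & ann@wearMask

  linMag <- sqrt(rowSums(lin^2))
  gyroMag <- sqrt(rowSums(rec@gyro^2))
  aHist <- magnitudeHistogram(linMag[keep], "accel")
  gHist <- magnitudeHistogram(gyroMag[keep], "gyro")
  mom <- tiltMoments(tilt)
  means <- magnitudeMeans(linMag[keep], gyroMag[keep])

  fs <- rec@samplingRate
  segs <- ann@segments
  segSeries <- function(x) apply(segs, 1, function(s) x[s[1]:(s[2] - 1)],
                                 simplify = FALSE)
  thFilled <- tilt@theta
  thFilled[!tilt@valid] <- mean(tilt@theta[tilt@valid])  # rare magnitude-floor gaps
  seAcc <- sampEnSignal(segSeries(linMag), sampEnParams("accel"), nativeFs = fs)
  seGyr <- sampEnSignal(segSeries(gyroMag), sampEnParams("gyro"), nativeFs = fs)
  seTilt <- sampEnSignal(segSeries(thFilled), sampEnParams("tilt"), nativeFs = fs)

  out <- c(mom["kurtosis"], mom["skewness"], mom["variance"],
           accel_ratio = accelRatio(aHist),
           gyro_ratio = gyroRatio(gHist, literal = literalGyroRatio),
           means,
           sampen_accel = seAcc@subjectValue,
           sampen_gyro = seGyr@subjectValue,
           sampen_tilt = seTilt@subjectValue,
           inactive_fraction = inactiveFraction(ann))
  names(out)[1:3] <- c("tilt_kurtosis", "tilt_skewness", "tilt_variance")
  attr(out, "accelHist") <- aHist
  attr(out, "gyroHist") <- gHist
  attr(out, "tiltHist") <- tiltHistogram(tilt)
  out
}

#' Assemble cohort features into a QOMEExperiment
#'
#' Applies [recordingFeatures()] to every recording and collects the
#' results as a [QOMEExperiment-class] (features x subjects), with the
#' clinical metadata and the impairment group assignment in `colData`.
#'
#' @param cohort a `qomeCohort` from [generateCohort()], or a list of
#'   [IMURecording-class] objects.
#' @param meta data.frame with columns `subject_id` and `uefm` (and
#'   optionally `bbt`); taken from the cohort when omitted.
#' @param config a [filterConfig()].
#' @param ... passed to [recordingFeatures()].
#' @return a [QOMEExperiment-class].
#' @export
cohortFeatures <- function(cohort, meta = NULL, config = filterConfig(), ...) {
  if (inherits(cohort, "qomeCohort")) {
    recordings <- cohort$recordings
    if (is.null(meta)) meta <- cohort$meta
  } else recordings <- cohort
  stopifnot(!is.null(meta), length(recordings) == nrow(meta))
  fmat <- vapply(recordings, function(r) {
    f <- recordingFeatures(r, config = config, ...)
    attributes(f)[c("accelHist", "gyroHist", "tiltHist")] <- NULL
    f
  }, numeric(11))
  colnames(fmat) <- meta$subject_id
  cd <- S4Vectors::DataFrame(meta[, setdiff(colnames(meta), "subject_id"),
                                  drop = FALSE],
                             row.names = meta$subject_id)
  cd$group <- assignGroups(cd$uefm)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = fmat), colData = cd)
  new("QOMEExperiment", se)
}

#' Plot group-averaged tilt-angle distributions
#'
#' Draws the per-group mean of the per-subject normalized 91-bin tilt
#' distributions (severe, moderate and mild impairment), the standard view
#' for judging postural stagnation versus diversity.
#'
#' @param tiltHists list of per-subject `tiltHistogram()` results.
#' @param groups integer group assignment (1 = severe, 2 = moderate,
#'   3 = mild), one per subject.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the 91 x 3 matrix of group-mean proportions.
#' @export
plotTiltDistribution <- function(tiltHists, groups, ...) {
  stopifnot(length(tiltHists) == length(groups))
  props <- vapply(tiltHists, function(h) h$normalized, numeric(91))
  gm <- vapply(sort(unique(groups)), function(g)
    rowMeans(props[, groups == g, drop = FALSE]), numeric(91))
  mids <- (tiltHists[[1]]$edges[-92] + tiltHists[[1]]$edges[-1]) / 2
  graphics::matplot(mids, gm, type = "l", lty = 1,
                    col = c("red", "darkgreen", "blue")[seq_len(ncol(gm))],
                    xlab = "Tilt angle (deg)", ylab = "Proportion", ...)
  graphics::legend("topright", legend = paste("Group", sort(unique(groups))),
                   col = c("red", "darkgreen", "blue")[seq_len(ncol(gm))],
                   lty = 1, bty = "n")
  invisible(gm)
}
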