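# Gravity removal, dropout removal and the two-threshold activity filter.

#' Activity-filter configuration
#'
#' @param thetaUse instantaneous-use threshold in G: a sample counts as
#'   "arm in use" (u = 1) where the gravity-subtracted acceleration
#'   magnitude exceeds `thetaUse` x 9.81 m/s^2. Default 0.1 G.
#' @param thetaActive windowed-fraction threshold in `[0, 1]`: a sample is
#'   kept (active) where the trailing mean U of u is at or above it.
#'   Default 0.1 (10%); 0 keeps every sample.
#' @param windowS trailing window length D in seconds for U. Default 10 s;
#'   realized as a boxcar of `round(windowS * samplingRate)` samples.
#' @param dropoutMinS constant-signal dropout rule: runs where all six
#'   sensor channels stay constant for longer than this many seconds are
#'   excluded from wear time. Default 180 s.
#' @param constantTol per-channel tolerance for "constant" in the dropout
#'   rule; default 0 (exact repetition).
#' @return a validated list of class `FilterConfig`.
#' @export
filterConfig <- function(thetaUse = 0.1, thetaActive = 0.1, windowS = 10,
                         dropoutMinS = 180, constantTol = 0) {
  if (thetaUse <= 0) stop("thetaUse must be positive")
  if (thetaActive < 0 || thetaActive > 1) stop("thetaActive must be in [0, 1]")
  if (windowS <= 0) stop("windowS must be positive")
  if (dropoutMinS <= 0) stop("dropoutMinS must be positive")
  structure(list(thetaUse = thetaUse, thetaActive = thetaActive,
                 windowS = windowS, dropoutMinS = dropoutMinS,
                 constantTol = constantTol),
            class = "FilterConfig")
}

#' Subtract gravity from the accelerometer signal
#'
#' Tracks the sensor orientation with a Madgwick-style complementary
#' filter (gradient-descent fusion of gyroscope integration and
#' accelerometer gravity alignment) and subtracts the gravity vector,
#' rotated into the sensor frame, from the measured acceleration. The
#' filter is initialized from the first accelerometer sample, so for a
#' static sensor the residual magnitude decays to the noise floor within
#' the first seconds.
#'
#' @param rec an [IMURecording-class].
#' @param beta Madgwick algorithm gain; default 0.1.
#' @param gravity gravitational acceleration, m/s^2.
#' @return n x 3 matrix of linear (gravity-free) acceleration, m/s^2.
#' @export
removeGravity <- function(rec, beta = 0.1, gravity = .GRAVITY) {
  stopifnot(is(rec, "IMURecording"))
  n <- length(rec@time)
  if (n < rec@samplingRate) stop("recording shorter than the filter convergence window (1 s)")
  # the filter's reference convention expects the accelerometer to read
  # +up at rest; this device convention reads the gravity vector itself
  a <- -rec@accel
  g <- rec@gyro * pi / 180
  q0 <- .tiltAlignQuaternion(a[1, ])
  up <- madgwick_up_cpp(a, g, 1 / rec@samplingRate, beta, q0)
  rec@accel + gravity * up
}

# quaternion (w,x,y,z) such that R(q)^T e3 equals the unit vector b
.tiltAlignQuaternion <- function(aFirst) {
  b <- aFirst / sqrt(sum(aFirst^2))
  e3 <- c(0, 0, 1)
  d <- sum(b * e3)
  if (d > 1 - 1e-9) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-9) return(c(0, 1, 0, 0))  # 180 deg about x
  ax <- c(b[2] * e3[3] - b[3] * e3[2],
          b[3] * e3[1] - b[1] * e3[3],
          b[1] * e3[2] - b[2] * e3[1])
  ax <- ax / sqrt(sum(ax^2))
  ang <- acos(d)
  c(cos(ang / 2), sin(ang / 2) * ax)
}

#' Drop constant-signal dropout periods
#'
#' Marks for removal every maximal run of samples over which all six sensor
#' channels stay constant (within `constantTol` per channel) for longer
#' than `dropoutMinS` seconds; shorter constant runs are kept.
#'
#' @param rec an [IMURecording-class].
#' @param dropoutMinS duration threshold in seconds; default 180 (3 min).
#' @param constantTol per-channel tolerance; default 0 (exact repetition).
#' @return logical wear mask per sample: `TRUE` = keep.
#' @export
dropConstantPeriods <- function(rec, dropoutMinS = 180, constantTol = 0) {
  stopifnot(is(rec, "IMURecording"))
  if (dropoutMinS <= 0) stop("dropoutMinS must be positive")
  n <- length(rec@time)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  ch <- cbind(rec@accel, rec@gyro)
  sameAsPrev <- rowSums(abs(ch[-1, , drop = FALSE] -
                            ch[-n, , drop = FALSE]) > constantTol) == 0
  r <- rle(sameAsPrev)
  pos <- cumsum(c(1, r$lengths))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    # a run of k TRUE pairs spans k + 1 constant samples
    nConst <- r$lengths[i] + 1
    if (nConst / rec@samplingRate > dropoutMinS) {
      first <- pos[i]                    # index of first sample of the run
      keep[first:(first + nConst - 1)] <- FALSE
    }
  }
  keep
}

# trailing boxcar mean with partial windows at the start
.trailingMean <- function(x, w) {
  n <- length(x)
  cs <- cumsum(x)
  lead <- c(rep(0, w), cs[seq_len(n - w)])
  denom <- pmin(seq_len(n), w)
  (cs - lead) / denom
}

# maximal runs of TRUE as a half-open (start, end) integer matrix
.maskSegments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keepRuns <- which(r$values)
  cbind(start = starts[keepRuns], end = ends[keepRuns] + 1L)
}

#' Two-threshold arm-activity filter
#'
#' Computes the binary instantaneous use score
#' `u = 1(||linear accel|| > thetaUse x 9.81)`, its trailing windowed mean
#' `U` over `windowS` seconds, and keeps the samples where
#' `U >= thetaActive`. Samples outside the wear mask (sensor dropout) are
#' excluded from both active and inactive time.
#'
#' @param linAccel n x 3 matrix of gravity-subtracted acceleration (m/s^2),
#'   or a numeric vector of its magnitudes.
#' @param samplingRate Hz.
#' @param config a [filterConfig()].
#' @param wearMask optional logical per-sample wear mask from
#'   [dropConstantPeriods()].
#' @return an [ActivityAnnotation-class].
#' @export
activityFilter <- function(linAccel, samplingRate, config = filterConfig(),
                           wearMask = NULL) {
  stopifnot(inherits(config, "FilterConfig"))
  mag <- if (is.matrix(linAccel)) sqrt(rowSums(linAccel^2)) else as.numeric(linAccel)
  n <- length(mag)
  w <- max(round(config$windowS * samplingRate), 1L)
  if (w > n) stop("window longer than the recording")
  if (is.null(wearMask)) wearMask <- rep(TRUE, n)
  stopifnot(length(wearMask) == n)
  u <- as.integer(mag > config$thetaUse * .GRAVITY)
  U <- .trailingMean(u, w)
  keep <- U >= config$thetaActive
  segs <- .maskSegments(keep & wearMask)
  new("ActivityAnnotation", u = u, U = U, keepMask = keep,
      segments = segs, samplingRate = samplingRate,
      config = unclass(config), wearMask = wearMask)
}

#' Grid search for the activity-filter thresholds
#'
#' Evaluates every pair on the `thetaUse` x `thetaActive` grid, computing
#' each subject's inactive fraction and its Pearson correlation with the
#' UEFM score across the cohort. Among the pairs whose correlation is
#' statistically significant (two-sided test at `alpha`), the most lenient
#' pair (lowest thresholds, i.e. retaining the most data) is selected.
#'
#' @param recordings list of [IMURecording-class], or a list of numeric
#'   vectors of precomputed gravity-subtracted acceleration magnitudes.
#' @param uefmScores numeric vector, one score per recording.
#' @param thetaUseGrid,thetaActiveGrid candidate thresholds; defaults span
#'   `[0.05, 0.30]` in steps of 0.05.
#' @param samplingRate Hz (used when magnitudes are supplied directly).
#' @param windowS trailing window length, seconds.
#' @param alpha significance level; default 0.05.
#' @return list with `surface` (data.frame `thetaUse`, `thetaActive`, `r`,
#'   `p`) and `selected` (named numeric of the chosen pair, or `NULL` with
#'   a warning when no pair reaches significance).
#' @export
gridSearchThresholds <- function(recordings, uefmScores,
                                 thetaUseGrid = seq(0.05, 0.30, by = 0.05),
                                 thetaActiveGrid = seq(0.05, 0.30, by = 0.05),
                                 samplingRate = .NATIVE_FS,
                                 windowS = 10, alpha = 0.05) {
  stopifnot(length(recordings) == length(uefmScores))
  if (length(recordings) < 3) stop("grid search needs at least 3 subjects")
  if (length(unique(uefmScores)) < 2) stop("UEFM scores must vary")
  mags <- lapply(recordings, function(r) {
    if (is(r, "IMURecording")) {
      samplingRate <<- r@samplingRate
      sqrt(rowSums(removeGravity(r)^2))
    } else as.numeric(r)
  })
  w <- max(round(windowS * samplingRate), 1L)
  rows <- expand.grid(thetaUse = thetaUseGrid, thetaActive = thetaActiveGrid)
  rows$r <- NA_real_
  rows$p <- NA_real_
  # U depends only on thetaUse; reuse it across the thetaActive axis
  for (tu in thetaUseGrid) {
    Us <- lapply(mags, function(m) .trailingMean(as.integer(m > tu * .GRAVITY), w))
    for (ta in thetaActiveGrid) {
      inact <- vapply(Us, function(U) mean(U < ta), 0)
      i <- which(rows$thetaUse == tu & rows$thetaActive == ta)
      if (sd(inact) > 0) {
        ct <- cor.test(inact, uefmScores)
        rows$r[i] <- unname(ct$estimate)
        rows$p[i] <- ct$p.value
      }
    }
  }
  sig <- which(!is.na(rows$p) & rows$p < alpha)
  if (!length(sig)) {
    warning("no threshold pair reached a significant correlation")
    selected <- NULL
  } else {
    lenient <- sig[order(rows$thetaUse[sig] + rows$thetaActive[sig],
                         rows$thetaActive[sig])]
    selected <- c(thetaUse = rows$thetaUse[lenient[1]],
                  thetaActive = rows$thetaActive[lenient[1]])
  }
  list(surface = rows, selected = selected)
}
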