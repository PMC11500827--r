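# Synthetic wrist-IMU cohort generator.
#
# The generator embeds, with known ground truth, the impairment gradients
# the downstream pipeline is designed to detect: active time, movement
# speed, tilt-distribution concentration and tilt-trajectory complexity all
# vary monotonically with the latent UEFM score.

.GRAVITY <- 9.81
.NATIVE_FS <- 52.6

# run code under a local, seeded RNG without disturbing the caller's stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a subject profile
#'
#' Builds a [SubjectProfile-class] either from explicitly supplied latent
#' parameters or, when they are omitted, from the UEFM score via the
#' cohort's default impairment gradients (see [generateCohort()]).
#'
#' @param subjectId character identifier.
#' @param uefm UEFM score in `[0, 66]`.
#' @param seed integer RNG seed for the recording.
#' @param activeFraction,tiltConcentration,complexityLevel,speedScale latent
#'   generator parameters; `NULL` = derive from `uefm` (without subject
#'   noise).
#' @param modeDeg modal tilt angle, degrees.
#' @param tiltScale affine scale of tilt excursions about the mode.
#' @param gyroNoiseScale multiplier on gyroscope sensor noise.
#' @return a [SubjectProfile-class].
#' @export
subjectProfile <- function(subjectId, uefm, seed,
                           activeFraction = NULL,
                           tiltConcentration = NULL,
                           complexityLevel = NULL,
                           speedScale = NULL,
                           modeDeg = 95, tiltScale = 1, gyroNoiseScale = 1) {
  maps <- .uefmMaps(uefm)
  new("SubjectProfile",
      subjectId = as.character(subjectId),
      uefm = as.numeric(uefm),
      activeFraction = if (is.null(activeFraction)) maps$activeFraction else activeFraction,
      tiltConcentration = if (is.null(tiltConcentration)) maps$tiltConcentration else tiltConcentration,
      complexityLevel = if (is.null(complexityLevel)) maps$complexityLevel else complexityLevel,
      speedScale = if (is.null(speedScale)) maps$speedScale else speedScale,
      modeDeg = modeDeg, tiltScale = tiltScale,
      gyroNoiseScale = gyroNoiseScale, seed = as.integer(seed))
}

# Default impairment gradients. Active time and movement speed rise gently
# and linearly across the whole UEFM range; tilt concentration falls
# steeply around UEFM 30 (hand function emerging ends postural stagnation)
# and tilt complexity rises steeply around UEFM 46 (regular daily hand use
# diversifies the posture trajectory). The two logistic transitions place
# the dominant group-1-vs-2 contrast on posture concentration and the
# dominant group-2-vs-3 contrast on posture complexity. `effects` selects
# which channels carry a systematic gradient; de-selected channels sit at
# their mid-range value (subject noise only).
.uefmMaps <- function(uefm, effects = c("activity", "posture",
                                        "complexity", "speed")) {
  list(
    activeFraction = if ("activity" %in% effects)
      0.20 + 0.20 * uefm / 66 else 0.30,
    tiltConcentration = if ("posture" %in% effects)
      0.15 + 0.60 * plogis((30 - uefm) / 2.0) else 0.35,
    complexityLevel = if ("complexity" %in% effects)
      0.10 + 0.72 * plogis((uefm - 46) / 5) else 0.35,
    speedScale = if ("speed" %in% effects)
      0.75 + 0.18 * uefm / 66 else 0.84
  )
}

# mixture tilt marginal: narrow stagnation peak + broad background, both
# scaled Betas on [0, 180] sharing the mode
.tiltMixture <- function(concentration, modeDeg) {
  m0 <- modeDeg / 180
  kPeak <- 400
  kBroad <- 2.6
  list(
    w = concentration,
    aPeak = m0 * (kPeak - 2) + 1, bPeak = (1 - m0) * (kPeak - 2) + 1,
    aBroad = m0 * (kBroad - 2) + 1, bBroad = (1 - m0) * (kBroad - 2) + 1
  )
}

# numeric quantile function of the mixture marginal (monotone interpolation
# of the CDF on a fine grid)
.tiltMixtureQuantile <- function(mix) {
  x <- seq(0, 1, length.out = 4097)
  cdf <- mix$w * pbeta(x, mix$aPeak, mix$bPeak) +
    (1 - mix$w) * pbeta(x, mix$aBroad, mix$bBroad)
  function(p) approx(cdf, x, xout = p, rule = 2, ties = "ordered")$y * 180
}

# alternating idle/active bout durations covering `duration` seconds
.boutPlan <- function(duration, activeFraction, meanActiveS = 40) {
  if (activeFraction <= 0) {
    return(data.frame(start = 0, end = duration, active = FALSE))
  }
  meanIdleS <- meanActiveS * (1 - activeFraction) / activeFraction
  sdlog <- 0.35
  draw <- function(mu) rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
  start <- 0
  active <- runif(1) < activeFraction
  rows <- list()
  while (start < duration) {
    len <- draw(if (active) meanActiveS else meanIdleS)
    end <- min(start + len, duration)
    rows[[length(rows) + 1]] <- data.frame(start = start, end = end, active = active)
    start <- end
    active <- !active
  }
  do.call(rbind, rows)
}

# Band-limited unit-variance AR(1): generated at `knotHz` knots
# (correlation time tauS) and spline-upsampled, keeping forearm angular
# rates in a physiological band instead of injecting sample-rate white
# noise.
.arSpline <- function(nSamples, dt, knotHz = 4, tauS = 1.0) {
  nK <- max(ceiling(nSamples * dt * knotHz) + 3, 4)
  phi <- exp(-1 / (knotHz * tauS))
  eK <- numeric(nK)
  eK[1] <- rnorm(1)
  innov <- rnorm(nK - 1, sd = sqrt(1 - phi^2))
  for (i in 2:nK) eK[i] <- phi * eK[i - 1] + innov[i - 1]
  stats::spline(x = (seq_len(nK) - 1) / knotHz, y = eK,
                xout = (seq_len(nSamples) - 1) * dt, method = "natural")$y
}

# Tilt trajectory for one active bout. Stochastic bouts follow a
# broadband posture walk (band-limited AR(1), probability-integral
# transformed through the normal CDF so it covers the whole posture
# distribution); oscillatory bouts follow a predictable slow oscillation
# over a random sub-interval of the posture distribution. The complexity
# level fixes the fraction of bouts that are stochastic (stratified
# across the recording, so the realized fraction matches the knob even in
# short recordings); per-window Sample Entropy of the tilt then rises
# roughly linearly in the complexity level, at physiological angular
# rates, while the pooled marginal stays anchored to the posture mixture.
.activeBoutTilt <- function(nSamples, dt, stochastic, q) {
  if (stochastic) {
    # walk over a random sub-interval: entropy is preserved (the SampEn
    # tolerance is window-SD-relative) while angular rates stay close to
    # the oscillatory mode, decoupling complexity from movement vigor
    w <- runif(1, 0.4, 0.7)
    c0 <- runif(1, w / 2, 1 - w / 2)
    u <- c0 + w * (pnorm(.arSpline(nSamples, dt, knotHz = 4, tauS = 0.5)) - 0.5)
    return(q(pmin(pmax(u, 1e-6), 1 - 1e-6)))
  }
  tt <- (seq_len(nSamples) - 1) * dt
  phase <- runif(1, 0, 2 * pi)
  amp <- runif(1, 0.25, 0.45)
  c0 <- runif(1, amp, 1 - amp)
  u <- c0 + amp * sin(2 * pi * 0.25 * tt + phase)
  q(pmin(pmax(u, 1e-6), 1 - 1e-6))
}

# Linear-acceleration bursts within an active bout: smooth sin^2 bumps
# with gamma-distributed peak magnitude. Burst directions are biased
# toward the local gravity axis (lifting/lowering movements dominate),
# which keeps the tilt-angle estimate — a projection of the measured
# acceleration — from being swamped by horizontal burst components.
.linearBursts <- function(nSamples, dt, speedScale, gapScale = 0.5,
                          thetaSeg = NULL) {
  lin <- matrix(0, nSamples, 3)
  i <- 1
  while (i <= nSamples) {
    gap <- round(rgamma(1, shape = 1, scale = gapScale) / dt)
    i <- i + max(gap, 1L)
    if (i > nSamples) break
    dur <- max(round(runif(1, 0.5, 1.8) / dt), 4L)
    peak <- rgamma(1, shape = 2, scale = 0.95 * speedScale)
    rnd <- rnorm(3)
    rnd <- rnd / sqrt(sum(rnd^2))
    if (is.null(thetaSeg)) {
      dir <- rnd
    } else {
      th <- thetaSeg[min(i, nSamples)]
      gv <- c(sin(th), 0, -cos(th)) * sample(c(-1, 1), 1)
      dir <- 0.9 * gv + 0.2 * rnd
      dir <- dir / sqrt(sum(dir^2))
    }
    idx <- i:min(i + dur - 1, nSamples)
    prof <- peak * sin(pi * seq_along(idx) / dur)^2
    # amplitude-proportional within-burst jitter (scale-invariant texture)
    prof <- prof * pmax(1 + 0.25 * rnorm(length(idx)), 0)
    lin[idx, ] <- lin[idx, ] + outer(prof, dir)
    i <- i + dur
  }
  lin
}

#' Generate one synthetic wrist-IMU recording
#'
#' Simulates a gravity-inclusive accelerometer and gyroscope time series
#' that alternates idle bouts (static posture + sensor noise) and active
#' bouts. Within active bouts the forearm tilt follows a latent trajectory
#' whose marginal distribution is a scaled-Beta mixture centered at the
#' modal tilt with concentration `tiltConcentration`, time-evolved as a
#' convex mixture (weight `complexityLevel`) of a broadband AR(1) process
#' and a slow 0.5 Hz oscillation; linear-acceleration bursts scaled by
#' `speedScale` are superimposed. The latent tilt trajectory and bout mask
#' are stored as ground truth.
#'
#' @param profile a [SubjectProfile-class].
#' @param duration recording length in seconds (> 0).
#' @param samplingRate Hz; default 52.6.
#' @param accelNoiseSD accelerometer noise SD per axis, m/s^2.
#' @param gyroNoiseSD gyroscope noise SD per axis, deg/s (scaled by the
#'   profile's `gyroNoiseScale`).
#' @return an [IMURecording-class] with `groundTruth` list(`tilt`, `active`).
#' @examples
#' p <- subjectProfile("S01", uefm = 40, seed = 1)
#' rec <- generateRecording(p, duration = 60)
#' rec
#' @export
generateRecording <- function(profile, duration,
                              samplingRate = .NATIVE_FS,
                              accelNoiseSD = 0.05, gyroNoiseSD = 0.5) {
  stopifnot(is(profile, "SubjectProfile"))
  if (duration <= 0) stop("duration must be positive")
  .withSeed(profile@seed, {
    fs <- samplingRate
    dt <- 1 / fs
    n <- max(round(duration * fs), 2L)
    tiltQ <- .tiltMixtureQuantile(
      .tiltMixture(profile@tiltConcentration, profile@modeDeg))
    plan <- .boutPlan(duration, profile@activeFraction)
    # stratified bout modes: the realized stochastic-bout fraction equals
    # the complexity level even in short recordings
    actIdx <- which(plan$active)
    nStoch <- round(profile@complexityLevel * length(actIdx))
    stochBout <- logical(nrow(plan))
    if (length(actIdx))
      stochBout[actIdx[sample.int(length(actIdx), nStoch)]] <- TRUE
    gapScale <- runif(1, 0.3, 0.65)   # per-subject movement-burst density

    tilt <- numeric(n)
    active <- logical(n)
    lin <- matrix(0, n, 3)
    for (b in seq_len(nrow(plan))) {
      i0 <- floor(plan$start[b] * fs) + 1
      i1 <- min(max(ceiling(plan$end[b] * fs), i0), n)
      idx <- i0:i1
      if (plan$active[b]) {
        # small periodic postural sway on top of the bout trajectory: real
        # arms are never still during activity, and a predictable sway
        # keeps narrow in-peak windows above the measurement-wobble floor
        # without injecting entropy of its own
        tb <- (seq_along(idx) - 1) * dt
        # amplitude fixed in measured space (the subject tilt-range scale
        # applied below must not push the sway under the sensor noise)
        sway <- (runif(1, 3, 5) / profile@tiltScale) *
          sin(2 * pi * runif(1, 0.2, 0.6) * tb + runif(1, 0, 2 * pi))
        tilt[idx] <- .activeBoutTilt(length(idx), dt, stochBout[b], tiltQ) + sway
        lin[idx, ] <- .linearBursts(length(idx), dt, profile@speedScale,
                                    gapScale, thetaSeg = tilt[idx] * pi / 180)
        active[idx] <- TRUE
      } else {
        # idle: arm parked near the modal posture (stagnation peak), with
        # a slow postural drift so parked stretches are not degenerate
        mix <- .tiltMixture(profile@tiltConcentration, profile@modeDeg)
        park <- 180 * qbeta(runif(1), mix$aPeak, mix$bPeak)
        drift <- 4 * .arSpline(length(idx), dt, knotHz = 0.15, tauS = 30)
        # respiratory-scale rocking of the parked arm: periodic, so it
        # reads as regular (low-entropy) posture, not sensor noise
        ti <- (seq_along(idx) - 1) * dt
        rock <- (runif(1, 2, 3.5) / profile@tiltScale) *
          sin(2 * pi * runif(1, 0.2, 0.35) * ti + runif(1, 0, 2 * pi))
        tilt[idx] <- park + drift + rock
      }
    }
    # per-subject postural range scale (affine about the mode), then a short
    # boxcar to avoid discontinuities at bout boundaries
    tilt <- profile@modeDeg + profile@tiltScale * (tilt - profile@modeDeg)
    tilt <- pmin(pmax(tilt, 0.5), 179.5)
    k <- 5
    tiltSm <- as.numeric(stats::filter(tilt, rep(1 / k, k), sides = 2))
    na <- is.na(tiltSm)
    tiltSm[na] <- tilt[na]   # keep raw values at the edges
    tilt <- tiltSm

    thetaR <- tilt * pi / 180
    agrav <- cbind(.GRAVITY * sin(thetaR), 0, -.GRAVITY * cos(thetaR))
    accel <- agrav + lin +
      matrix(rnorm(3 * n, sd = accelNoiseSD), n, 3)

    gyroY <- c(0, diff(tilt)) / dt          # pitch rate, deg/s
    gyr <- cbind(0, gyroY, 0)
    if (any(active)) {
      # incidental rotation about the world vertical (arm swivel /
      # shoulder rotation) during activity: smooth, impairment-
      # independent, per-subject amplitude. It leaves gravity and hence
      # the tilt angle untouched but enters the angular-velocity
      # magnitude on all sensor axes.
      yawAmp <- exp(runif(1, log(25), log(140)))
      yawRate <- yawAmp * .arSpline(n, dt, knotHz = 6, tauS = 0.3) * active
      gyr <- gyr + yawRate * cbind(-sin(thetaR), 0, cos(thetaR))
      # micro-rotation floor: a wrist in use is never rotation-still;
      # small fast adjustments on every axis, per-subject amplitude
      microAmp <- runif(1, 8, 20)
      for (ax in 1:3)
        gyr[, ax] <- gyr[, ax] +
          microAmp * .arSpline(n, dt, knotHz = 6, tauS = 0.3) * active
    }
    gyr <- gyr +
      matrix(rnorm(3 * n, sd = gyroNoiseSD * profile@gyroNoiseScale), n, 3)

    new("IMURecording",
        subjectId = profile@subjectId, samplingRate = fs,
        time = (seq_len(n) - 1) * dt,
        accel = accel, gyro = gyr,
        groundTruth = list(tilt = tilt, active = active))
  })
}

#' Generate a synthetic stroke cohort
#'
#' Draws `n` subjects with UEFM scores spread over `uefmRange` (evenly
#' spaced with jitter, so each impairment group stays populated), maps each
#' score through the default impairment gradients plus independent subject
#' noise, and simulates one recording per subject. Active fraction and
#' movement speed rise gently with UEFM; tilt concentration falls steeply
#' near UEFM 30 and tilt complexity rises steeply near UEFM 47, so the
#' cohort embeds, with known ground truth, the qualitative pattern the
#' pipeline is meant to recover.
#'
#' @param n number of subjects (>= 2).
#' @param uefmRange length-2 numeric interval for UEFM scores.
#' @param seed integer master seed; all randomness derives from it.
#' @param duration per-subject recording length in seconds.
#' @param samplingRate Hz.
#' @param effects which latent channels carry a systematic UEFM gradient
#'   (any of `"activity"`, `"posture"`, `"complexity"`, `"speed"`);
#'   de-selected channels keep subject noise around a mid-range value.
#'   Restricting the injected effects to the posture channels is the
#'   configuration used to study whether the cohort statistics recover
#'   them.
#' @return a list of class `qomeCohort` with elements `profiles` (list of
#'   [SubjectProfile-class]), `recordings` (list of [IMURecording-class])
#'   and `meta` (data.frame `subject_id`, `uefm`, `bbt`).
#' @examples
#' coh <- generateCohort(4, uefmRange = c(15, 60), seed = 7, duration = 30)
#' coh$meta
#' @export
generateCohort <- function(n, uefmRange = c(10, 65), seed,
                           duration = 1200, samplingRate = .NATIVE_FS,
                           effects = c("activity", "posture",
                                       "complexity", "speed")) {
  if (n < 2) stop("a cohort needs at least 2 subjects")
  stopifnot(length(uefmRange) == 2, uefmRange[1] < uefmRange[2])
  .withSeed(seed, {
    u <- seq(uefmRange[1], uefmRange[2], length.out = n) + rnorm(n, sd = 2)
    u <- round(pmin(pmax(u, uefmRange[1]), uefmRange[2]))
    u <- u[order(u)]
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    profiles <- vector("list", n)
    for (i in seq_len(n)) {
      maps <- .uefmMaps(u[i], effects)
      profiles[[i]] <- subjectProfile(
        subjectId = sprintf("S%02d", i), uefm = u[i], seed = seeds[i],
        activeFraction = min(max(maps$activeFraction + rnorm(1, sd = 0.03), 0.05), 0.9),
        tiltConcentration = min(max(maps$tiltConcentration + rnorm(1, sd = 0.035), 0.02), 0.95),
        complexityLevel = min(max(maps$complexityLevel + rnorm(1, sd = 0.04), 0.02), 0.98),
        speedScale = min(max(maps$speedScale + rnorm(1, sd = 0.12), 0.3), 2),
        modeDeg = 95 + rnorm(1, sd = 4),
        tiltScale = min(max(rnorm(1, 1, 0.35), 0.5), 1.9),
        gyroNoiseScale = min(max(rlnorm(1, 0, 0.3), 0.4), 2.5)
      )
    }
    # BBT: ~0 blocks below UEFM 30 (no hand function), then rising
    bbt <- ifelse(u < 30, rbinom(n, 2, 0.3),
                  round(pmin(pmax((u - 27) * 1.05 + rnorm(n, sd = 4), 0), 60)))
    recordings <- lapply(profiles, generateRecording,
                         duration = duration, samplingRate = samplingRate)
    structure(
      list(profiles = profiles, recordings = recordings,
           meta = data.frame(subject_id = vapply(profiles, slot, "", "subjectId"),
                             uefm = u, bbt = as.integer(bbt))),
      class = "qomeCohort")
  })
}

#' @export
print.qomeCohort <- function(x, ...) {
  cat("qomeCohort: ", length(x$recordings), " subjects, UEFM range [",
      min(x$meta$uefm), ", ", max(x$meta$uefm), "]\n", sep = "")
  invisible(x)
}

#' Read and write IMU recordings as CSV
#'
#' The on-disk format is a plain CSV with header
#' `t,ax,ay,az,gx,gy,gz`: time in seconds, acceleration in m/s^2
#' (gravity-inclusive), angular velocity in deg/s.
#'
#' @param rec an [IMURecording-class].
#' @param path file path.
#' @return `readRecordingCSV` returns an [IMURecording-class];
#'   `writeRecordingCSV` returns `path` invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "IMURecording"))
  df <- data.frame(t = rec@time,
                   ax = rec@accel[, 1], ay = rec@accel[, 2], az = rec@accel[, 3],
                   gx = rec@gyro[, 1], gy = rec@gyro[, 2], gz = rec@gyro[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordingCSV
#' @param subjectId identifier for the returned recording.
#' @param samplingRate Hz; `NULL` = inferred from the median timestamp step.
#' @export
readRecordingCSV <- function(path, subjectId = basename(path),
                             samplingRate = NULL) {
  df <- read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% colnames(df)))
    stop("CSV must have columns ", paste(need, collapse = ","))
  if (is.null(samplingRate))
    samplingRate <- 1 / stats::median(diff(df$t))
  new("IMURecording", subjectId = subjectId, samplingRate = samplingRate,
      time = df$t, accel = as.matrix(df[, c("ax", "ay", "az")]),
      gyro = as.matrix(df[, c("gx", "gy", "gz")]))
}

#' Write a synthetic cohort to a directory
#'
#' Writes one `<subject_id>.csv` per recording, a `cohort.csv` metadata
#' table (`subject_id,uefm,bbt`) and a `ground_truth.json` with each
#' subject's latent generator parameters.
#'
#' @param cohort a `qomeCohort` from [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "qomeCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$recordings)
    writeRecordingCSV(rec, file.path(dir, paste0(rec@subjectId, ".csv")))
  write.csv(cohort$meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  gt <- lapply(cohort$profiles, function(p) list(
    subject_id = p@subjectId, uefm = p@uefm,
    active_fraction = p@activeFraction,
    tilt_concentration = p@tiltConcentration,
    complexity_level = p@complexityLevel,
    speed_scale = p@speedScale, seed = p@seed))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
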