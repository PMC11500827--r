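# Independent oracles, written before (and kept independent of) the
# implementations they check.

# Brute-force Sample Entropy: restricted Richman-Moorman estimator with
# explicit loops. Templates of length m and m+1 are both counted over the
# starting indices 1..(n-m); Chebyshev distance, tolerance <=, self-matches
# excluded.
sampenBrute <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0L
  A <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Direct enumeration of the two-threshold activity filter: per-sample
# trailing-window mean computed naively.
activityMaskBrute <- function(mag, fs, thetaUse, thetaActive, windowS) {
  u <- as.integer(mag > thetaUse * 9.81)
  w <- max(round(windowS * fs), 1)
  n <- length(u)
  U <- numeric(n)
  for (t in seq_len(n)) U[t] <- mean(u[max(1, t - w + 1):t])
  list(u = u, U = U, keep = U >= thetaActive)
}

# Static recording: constant gravity-only accelerometer plus optional noise.
staticRecording <- function(duration = 20, fs = 52.6,
                            accelVec = c(0, 0, -9.81), noiseSD = 0) {
  n <- round(duration * fs)
  acc <- matrix(rep(accelVec, each = n), n, 3)
  if (noiseSD > 0) acc <- acc + matrix(rnorm(3 * n, sd = noiseSD), n, 3)
  new("IMURecording", subjectId = "static", samplingRate = fs,
      time = (seq_len(n) - 1) / fs, accel = acc, gyro = matrix(0, n, 3))
}

# Recording that rotates 90 degrees about the sensor Y axis between two
# static phases, with a dynamically consistent gyroscope.
rotationRecording <- function(duration = 20, fs = 52.6,
                              rotStart = 8, rotDur = 4) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  theta <- pmin(pmax((t - rotStart) / rotDur, 0), 1) * 90
  thr <- theta * pi / 180
  acc <- cbind(9.81 * sin(thr), 0, -9.81 * cos(thr))
  gyr <- cbind(0, c(0, diff(theta)) * fs, 0)
  new("IMURecording", subjectId = "rot", samplingRate = fs,
      time = t, accel = acc, gyro = gyr)
}

# Static gravity plus a sinusoidal linear acceleration on the X axis.
sinusoidRecording <- function(duration = 30, fs = 52.6, amp = 1, freq = 1.5) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  acc <- cbind(amp * sin(2 * pi * freq * t), 0, rep(-9.81, n))
  new("IMURecording", subjectId = "sin", samplingRate = fs,
      time = t, accel = acc, gyro = matrix(0, n, 3))
}
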