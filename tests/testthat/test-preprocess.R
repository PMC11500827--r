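test_that("gravity removal drives a static recording to the noise floor", {
  rec <- staticRecording(duration = 20)
  lin <- removeGravity(rec)
  after5 <- lin[rec@time > 5, ]
  expect_lt(max(sqrt(rowSums(after5^2))), 0.1)
  expect_error(removeGravity(staticRecording(duration = 0.5)), "convergence")
})

test_that("gravity removal tracks a 90-degree rotation", {
  rec <- rotationRecording(duration = 20, rotStart = 8, rotDur = 4)
  lin <- removeGravity(rec)
  mag <- sqrt(rowSums(lin^2))
  t <- rec@time
  expect_lt(max(mag[t > 5 & t < 7.8]), 0.1)   # first static phase
  expect_lt(max(mag[t > 14]), 0.1)            # second static phase
})

test_that("an injected sinusoidal burst is recovered within 10% amplitude", {
  amp <- 1
  rec <- sinusoidRecording(duration = 30, amp = amp, freq = 1.5)
  lin <- removeGravity(rec)
  sel <- rec@time > 5
  tt <- rec@time[sel]
  x <- lin[sel, 1]
  rec_amp <- 2 * sqrt(mean(x * sin(2 * pi * 1.5 * tt))^2 +
                      mean(x * cos(2 * pi * 1.5 * tt))^2)
  expect_lt(abs(rec_amp - amp) / amp, 0.1)
})

test_that("constant-signal dropout follows the duration rule", {
  fs <- 10
  n <- 10 * 60 * fs            # 10 minutes
  set.seed(21)
  acc <- matrix(rnorm(3 * n), n, 3)
  gyr <- matrix(rnorm(3 * n), n, 3)
  blockIdx <- function(fromMin, toMin) (fromMin * 60 * fs + 1):(toMin * 60 * fs)
  i4 <- blockIdx(2, 6)         # 4-minute constant block
  acc[i4, ] <- rep(c(1, 2, 3), each = length(i4))
  gyr[i4, ] <- 0
  rec <- new("IMURecording", subjectId = "d", samplingRate = fs,
             time = (seq_len(n) - 1) / fs, accel = acc, gyro = gyr)
  keep <- dropConstantPeriods(rec, dropoutMinS = 180)
  expect_true(all(!keep[i4[-1]]))            # block dropped
  expect_true(all(keep[-i4]))                # everything else kept

  # 2-minute constant block stays
  acc2 <- matrix(rnorm(3 * n), n, 3)
  i2 <- blockIdx(2, 4)
  acc2[i2, ] <- 0.5
  rec2 <- new("IMURecording", subjectId = "d2", samplingRate = fs,
              time = (seq_len(n) - 1) / fs, accel = acc2,
              gyro = matrix(rnorm(3 * n), n, 3))
  expect_true(all(dropConstantPeriods(rec2, 180)))

  # no two adjacent samples equal -> vacuous
  rec3 <- new("IMURecording", subjectId = "d3", samplingRate = fs,
              time = (seq_len(n) - 1) / fs,
              accel = matrix(seq_len(3 * n) * 1.0, n, 3),
              gyro = matrix(rnorm(3 * n), n, 3))
  expect_true(all(dropConstantPeriods(rec3, 180)))
})

test_that("activity filter matches the enumeration oracle on square waves", {
  fs <- 52.6
  for (cfgvals in list(c(0.1, 0.1, 10), c(0.2, 0.25, 10), c(0.05, 0.3, 5))) {
    onG <- 0.3
    period <- 20
    n <- round(200 * fs)
    t <- (seq_len(n) - 1) / fs
    mag <- ifelse(t %% (2 * period) < period, onG * 9.81, 0)
    oracle <- activityMaskBrute(mag, fs, cfgvals[1], cfgvals[2], cfgvals[3])
    ann <- activityFilter(mag, fs,
                          filterConfig(thetaUse = cfgvals[1],
                                       thetaActive = cfgvals[2],
                                       windowS = cfgvals[3]))
    expect_identical(as.integer(ann@u), oracle$u)
    expect_equal(ann@U, oracle$U, tolerance = 1e-12)
    expect_identical(keepMask(ann), oracle$keep)
  }
})

test_that("degenerate activity-filter inputs behave as specified", {
  fs <- 52.6
  zero <- rep(0, round(60 * fs))
  ann <- activityFilter(zero, fs, filterConfig())
  expect_equal(inactiveFraction(ann), 1)
  expect_equal(nrow(activeSegments(ann)), 0)
  # zero threshold keeps everything
  ann2 <- activityFilter(zero, fs, filterConfig(thetaActive = 0))
  expect_equal(inactiveFraction(ann2), 0)
  expect_error(activityFilter(rep(1, 10), fs, filterConfig(windowS = 10)),
               "window longer")
  # totals partition wear time
  set.seed(22)
  mag <- abs(rnorm(round(120 * fs), sd = 1.5))
  ann3 <- activityFilter(mag, fs, filterConfig())
  expect_equal(totalActiveS(ann3) + totalInactiveS(ann3),
               length(mag) / fs, tolerance = 1e-9)
})

test_that("raising either threshold never increases active time", {
  set.seed(23)
  fs <- 52.6
  mag <- abs(rnorm(round(300 * fs), sd = 1.2))
  base <- activityFilter(mag, fs, filterConfig(thetaUse = 0.1, thetaActive = 0.1))
  upUse <- activityFilter(mag, fs, filterConfig(thetaUse = 0.2, thetaActive = 0.1))
  upAct <- activityFilter(mag, fs, filterConfig(thetaUse = 0.1, thetaActive = 0.2))
  expect_lte(sum(upUse@u), sum(base@u))
  expect_lte(totalActiveS(upAct), totalActiveS(base))
  expect_lte(totalActiveS(upUse), totalActiveS(base))
  # keep mask is a pure function of U and the threshold (idempotence)
  again <- activityFilter(mag, fs, filterConfig(thetaUse = 0.1, thetaActive = 0.1))
  expect_identical(keepMask(again), keepMask(base))
})

test_that("threshold grid search selects the most lenient significant pair", {
  set.seed(24)
  coh <- generateCohort(10, c(10, 65), seed = 301, duration = 600)
  mags <- lapply(coh$recordings, function(r) sqrt(rowSums(removeGravity(r)^2)))
  gs <- gridSearchThresholds(mags, coh$meta$uefm)
  expect_equal(nrow(gs$surface), 36)          # 6 x 6 grid
  expect_false(is.null(gs$selected))
  sel <- gs$surface[gs$surface$thetaUse == gs$selected["thetaUse"] &
                    gs$surface$thetaActive == gs$selected["thetaActive"], ]
  expect_lt(sel$p, 0.05)
  expect_lt(sel$r, 0)                         # inactive time falls with UEFM
  # no significant pair anywhere more lenient
  better <- gs$surface$thetaUse + gs$surface$thetaActive <
    sum(gs$selected) - 1e-9
  expect_true(all(is.na(gs$surface$p[better]) | gs$surface$p[better] >= 0.05))

  # identical recordings: zero variance -> null selection with a warning
  same <- rep(list(mags[[1]]), 4)
  expect_warning(gs0 <- gridSearchThresholds(same, c(10, 20, 30, 40)),
                 "no threshold pair")
  expect_null(gs0$selected)
  expect_error(gridSearchThresholds(mags[1:2], c(1, 2)), "at least 3")
})
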