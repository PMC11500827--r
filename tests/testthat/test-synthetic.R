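test_that("identical profiles reproduce identical recordings bit for bit", {
  p <- subjectProfile("S1", uefm = 33, seed = 12345)
  r1 <- generateRecording(p, duration = 60)
  r2 <- generateRecording(p, duration = 60)
  expect_identical(accel(r1), accel(r2))
  expect_identical(gyro(r1), gyro(r2))
  expect_identical(groundTruth(r1), groundTruth(r2))
  c1 <- generateCohort(3, c(20, 60), seed = 99, duration = 30)
  c2 <- generateCohort(3, c(20, 60), seed = 99, duration = 30)
  expect_identical(c1$meta, c2$meta)
  expect_identical(accel(c1$recordings[[2]]), accel(c2$recordings[[2]]))
  # generation does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generateRecording(p, 10)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a fully idle profile stays at gravity magnitude", {
  p <- subjectProfile("idle", uefm = 20, seed = 5, activeFraction = 0)
  rec <- generateRecording(p, duration = 300)
  expect_false(any(groundTruth(rec)$active))
  dev <- abs(sqrt(rowSums(accel(rec)^2)) - 9.81)
  # noise-only deviations: ~99.7% within 3 sensor-noise SDs
  expect_lt(mean(dev > 3 * 0.05), 0.005)
  expect_lt(max(dev), 6 * 0.05)
})

test_that("empirical active time converges to the profile fraction", {
  p <- subjectProfile("af", uefm = 40, seed = 6, activeFraction = 0.35)
  rec <- generateRecording(p, duration = 1800)   # 30 simulated minutes
  expect_lt(abs(mean(groundTruth(rec)$active) - 0.35), 0.05)
})

test_that("profile invariants and argument errors are enforced", {
  expect_error(generateRecording(subjectProfile("x", 30, 1), duration = 0),
               "positive")
  expect_error(subjectProfile("x", uefm = 70, seed = 1), "uefm")
  expect_error(subjectProfile("x", uefm = 30, seed = 1,
                              activeFraction = 1.2), "activeFraction")
  expect_error(generateCohort(1, c(10, 60), seed = 1), "at least 2")
})

test_that("cohort gradients embed the claimed impairment structure", {
  coh <- generateCohort(30, c(10, 65), seed = 777, duration = 10)
  u <- coh$meta$uefm
  conc <- vapply(coh$profiles, slot, 0, "tiltConcentration")
  lam <- vapply(coh$profiles, slot, 0, "complexityLevel")
  af <- vapply(coh$profiles, slot, 0, "activeFraction")
  expect_lt(cor(u, conc, method = "spearman"), 0)
  expect_gt(cor(u, lam, method = "spearman"), 0)
  expect_gt(cor(u, af, method = "spearman"), 0)
  expect_true(all(u >= 10 & u <= 65))
  # severe subjects have essentially no hand function on the BBT
  expect_true(all(coh$meta$bbt[u < 30] <= 2))
  # two-subject boundary case
  c2 <- generateCohort(2, c(20, 50), seed = 11, duration = 5)
  expect_equal(length(c2$recordings), 2)
})

test_that("switching off a gradient channel flattens it", {
  coh <- generateCohort(20, c(10, 65), seed = 778, duration = 5,
                        effects = c("activity", "posture", "complexity"))
  sp <- vapply(coh$profiles, slot, 0, "speedScale")
  expect_lt(abs(cor(coh$meta$uefm, sp)), 0.5)   # noise only
  conc <- vapply(coh$profiles, slot, 0, "tiltConcentration")
  expect_lt(cor(coh$meta$uefm, conc), -0.8)
})

test_that("a narrowly concentrated profile parks near the 95-degree mode", {
  p <- subjectProfile("narrow", uefm = 12, seed = 8,
                      tiltConcentration = 0.95, activeFraction = 0.5)
  rec <- generateRecording(p, duration = 600)
  gt <- groundTruth(rec)
  tilts <- gt$tilt[gt$active]
  # bulk of the posture mass in a narrow band about the mode
  expect_gt(mean(abs(tilts - 95) < 15), 0.8)
  expect_lt(abs(stats::median(tilts) - 95), 8)
})

test_that("recordings round-trip through the CSV interface", {
  p <- subjectProfile("S9", uefm = 50, seed = 13)
  rec <- generateRecording(p, duration = 20)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "S9.csv")
  writeRecordingCSV(rec, path)
  back <- readRecordingCSV(path, subjectId = "S9")
  expect_equal(accel(back), accel(rec), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(gyro(back), gyro(rec), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(samplingRate(back), samplingRate(rec), tolerance = 1e-3)
})

test_that("cohorts are written with metadata and ground truth", {
  coh <- generateCohort(3, c(20, 60), seed = 21, duration = 10)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt), 3)
  expect_equal(gt[[1]]$uefm, coh$meta$uefm[1])
  meta <- read.csv(file.path(dir, "cohort.csv"))
  expect_identical(sort(paste0(meta$subject_id, ".csv")),
                   sort(setdiff(list.files(dir), c("cohort.csv", "ground_truth.json"))))
})

test_that("recording objects validate their invariants", {
  expect_error(new("IMURecording", subjectId = "b", samplingRate = 50,
                   time = c(0, 0.02, 0.01), accel = matrix(0, 3, 3),
                   gyro = matrix(0, 3, 3)), "increasing")
  expect_error(new("IMURecording", subjectId = "b", samplingRate = 50,
                   time = c(0, 0.02), accel = matrix(0, 3, 3),
                   gyro = matrix(0, 3, 3)), "equal length")
  expect_error(new("IMURecording", subjectId = "b", samplingRate = 50,
                   time = c(0, 1 / 50), accel = matrix(c(NA, 0, 0, 0, 0, 0), 2, 3),
                   gyro = matrix(0, 2, 3)), "finite")
})
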