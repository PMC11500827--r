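test_that("SampEn kernel agrees exactly with the brute-force oracle", {
  set.seed(11)
  for (k in 1:60) {
    n <- sample(10:60, 1)
    m <- sample(1:4, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                sample(1:4, n, replace = TRUE) * 1.0,
                cumsum(rnorm(n)))
    r <- runif(1, 0.05, 0.6) * max(sd(x), 0.1)
    expected <- sampenBrute(x, m, r)
    got <- sampEn(x, m, r)
    if (is.na(expected)) expect_true(is.na(got)) else expect_identical(got, expected)
  }
})

test_that("constant series has zero entropy and short series error", {
  expect_identical(sampEn(rep(1, 50), m = 2, rAbs = 0.1), 0)
  expect_identical(sampEn(rep(-3.2, 20), m = 4, rAbs = 1e-9), 0)
  expect_error(sampEn(1:3, m = 2, rAbs = 0.1), "too short")
})

test_that("i.i.d. noise is more entropic than a sinusoid at matched settings", {
  set.seed(12)
  wins <- replicate(50, {
    n <- 300
    noise <- runif(n)
    sine <- sin(2 * pi * 3 * seq_len(n) / n + runif(1, 0, 2 * pi))
    sn <- sampEn(noise, m = 2, rAbs = 0.25 * sd(noise))
    ss <- sampEn(sine, m = 2, rAbs = 0.25 * sd(sine))
    sn > ss
  })
  # one-sided sign test at alpha 1e-6: noise wins essentially always
  expect_gte(sum(wins), 45)
})

test_that("SD-relative tolerance makes the windowed entropy scale-invariant", {
  set.seed(13)
  x <- cumsum(rnorm(600))
  p <- sampEnParams("tilt", N = 200)
  a <- sampEnSignal(x, p, nativeFs = 52.6)
  b <- sampEnSignal(1000 * x, p, nativeFs = 52.6)
  expect_equal(a@values, b@values, tolerance = 1e-12)
  expect_equal(subjectValue(a), subjectValue(b), tolerance = 1e-12)
})

test_that("kernel matches pracma's estimator on continuous data", {
  skip_if_not_installed("pracma")
  set.seed(14)
  for (k in 1:20) {
    x <- rnorm(150)
    r <- 0.3 * sd(x)
    # pracma uses a strict inequality; ties have probability zero here
    expect_equal(sampEn(x, 2, r), pracma::sample_entropy(x, edim = 2, r = r),
                 tolerance = 1e-12)
  }
})

test_that("per-signal defaults carry the reference parameters", {
  pa <- sampEnParams("accel")
  expect_equal(unlist(pa[c("m", "r", "N", "fs")]),
               c(m = 2, r = 0.25, N = 250, fs = 26))
  pg <- sampEnParams("gyro")
  expect_equal(unlist(pg[c("m", "r", "N", "fs")]),
               c(m = 5, r = 0.40, N = 750, fs = 52.6))
  pt <- sampEnParams("tilt")
  expect_equal(unlist(pt[c("m", "r", "N", "fs")]),
               c(m = 3, r = 0.35, N = 250, fs = 52.6))
  expect_error(sampEnParams("tilt", N = 3), "exceed")
})

test_that("segmentation, decimation and undefined windows behave as specified", {
  set.seed(15)
  # decimation keeps every k-th sample: a signal alternating around a slow
  # ramp is constant after decimation by 2 -> zero entropy
  n <- 500
  x <- rep(c(0, 1), length.out = n)
  p <- sampEnParams("accel", m = 2, r = 0.2, N = 100, fs = 26)
  res <- sampEnSignal(x, p, nativeFs = 52.6)
  expect_true(all(res@values == 0))
  # segments shorter than N (after decimation) are discarded
  segs <- list(rnorm(30), rnorm(600))
  p2 <- sampEnParams("tilt", N = 250)
  res2 <- sampEnSignal(segs, p2, nativeFs = 52.6)
  expect_equal(length(res2@values), 2)   # only the long segment, 2 windows
  # no segment long enough -> empty result
  res3 <- sampEnSignal(list(rnorm(100)), p2, nativeFs = 52.6)
  expect_equal(res3@nSegmentsUsed, 0L)
  expect_true(is.na(subjectValue(res3)))
})

test_that("entropy rises with the generator's complexity level", {
  set.seed(16)
  lam <- seq(0.05, 0.95, length.out = 30)
  vals <- vapply(seq_along(lam), function(i) {
    p <- subjectProfile(paste0("c", i), uefm = 40, seed = 9000 + i,
                        complexityLevel = lam[i], activeFraction = 0.6,
                        tiltConcentration = 0.2)
    rec <- generateRecording(p, duration = 360)
    gt <- groundTruth(rec)
    segs <- wristqome:::.maskSegments(gt$active)
    sl <- apply(segs, 1, function(s) gt$tilt[s[1]:(s[2] - 1)],
                simplify = FALSE)
    subjectValue(sampEnSignal(sl, sampEnParams("tilt"), nativeFs = 52.6))
  }, 0)
  expect_gte(cor(lam, vals, method = "spearman"), 0.8)
})

test_that("parameter grid search maximizes the UEFM correlation", {
  set.seed(17)
  # singleton grid returns the defaults
  sig <- lapply(1:5, function(i) rnorm(600))
  gs <- sampEnGridSearch(sig, uefmScores = c(10, 20, 30, 40, 50),
                         signal = "tilt")
  expect_equal(gs$best$m, 3L)
  expect_equal(nrow(gs$table), 1)
  # identical signals across subjects -> zero entropy variance -> error
  same <- rep(list(sin(1:600 / 5)), 4)
  expect_error(sampEnGridSearch(same, c(10, 20, 30, 40), signal = "tilt"),
               "no parameter combination")
  expect_error(sampEnGridSearch(sig[1:2], c(1, 2), signal = "tilt"),
               "at least 3")
})

test_that("grid search returns the argmax of independently recomputed correlations", {
  set.seed(18)
  # subjects mix regular oscillation and broadband segments in an
  # impairment-dependent ratio; every grid row must match a direct,
  # independent evaluation and the selection must be its argmax
  uefm <- seq(10, 60, length.out = 10)
  fs <- 52.6
  signals <- lapply(seq_along(uefm), function(i) {
    frac <- 0.1 + 0.8 * (uefm[i] - 10) / 50
    lapply(1:10, function(k) {
      tt <- (0:299) / fs
      if (runif(1) < frac) {
        kn <- rnorm(15)
        stats::spline((seq_along(kn) - 1) / 2, kn, xout = tt,
                      method = "natural")$y
      } else sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))
    })
  })
  grid <- expand.grid(m = c(2L, 3L), r = c(0.2, 0.35), fs = c(52.6, 13))
  gs <- sampEnGridSearch(signals, uefm, signal = "tilt",
                         mGrid = c(2L, 3L), rGrid = c(0.2, 0.35),
                         NGrid = 60L, fsGrid = c(52.6, 13))
  direct <- vapply(seq_len(nrow(grid)), function(i) {
    p <- sampEnParams("tilt", m = grid$m[i], r = grid$r[i], N = 60L,
                      fs = grid$fs[i])
    v <- vapply(signals, function(s)
      subjectValue(sampEnSignal(s, p, nativeFs = fs)), 0)
    cor(v, uefm)
  }, 0)
  expect_equal(gs$table$r_uefm, direct, tolerance = 1e-12)
  bi <- which.max(direct)
  expect_equal(gs$best$m, grid$m[bi])
  expect_equal(gs$best$r, grid$r[bi])
  expect_equal(gs$best$fs, grid$fs[bi])
  # the mixture construction itself correlates positively at every rate
  expect_true(all(direct > 0))
})
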