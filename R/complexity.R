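# Sample Entropy of movement signals.

#' Sample Entropy of a scalar series
#'
#' Richman-Moorman Sample Entropy: with B the number of template pairs of
#' length `m` within Chebyshev distance `rAbs` of each other and A the
#' number of those pairs that still match at length `m + 1` (self-matches
#' excluded, both lengths counted over the same template index set),
#' SampEn = -ln(A / B), in nats. Higher values indicate a less regular
#' signal. Returns `NA` (undefined) when either count is zero.
#'
#' @param x numeric series, `length(x) > m + 1`.
#' @param m template length in samples.
#' @param rAbs absolute tolerance, same units as `x`.
#' @return entropy in nats, or `NA` when undefined.
#' @examples
#' sampEn(rep(1, 50), m = 2, rAbs = 0.1)  # fully regular: 0
#' @export
sampEn <- function(x, m, rAbs) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short for template length m")
  sampen_cpp(x, as.integer(m), rAbs)
}

#' Per-signal Sample Entropy parameter defaults
#'
#' The parameter combinations that maximized the entropy-impairment
#' correlation for each signal in the reference analysis: acceleration
#' magnitude m = 2, r = 0.25, N = 250, 26 Hz; angular-velocity magnitude
#' m = 5, r = 0.4, N = 750, 52.6 Hz; tilt angle m = 3, r = 0.35, N = 250,
#' 52.6 Hz. The tolerance `r` is relative to each window's SD.
#'
#' @param signal `"accel"`, `"gyro"` or `"tilt"`.
#' @param m,r,N,fs overrides for the template length (samples), relative
#'   tolerance, segmentation length (samples) and analysis sampling rate
#'   (Hz; one of 52.6, 26, 13).
#' @return list of class `SampEnParams`.
#' @export
sampEnParams <- function(signal = c("accel", "gyro", "tilt"),
                         m = NULL, r = NULL, N = NULL, fs = NULL) {
  signal <- match.arg(signal)
  def <- switch(signal,
    accel = list(m = 2L, r = 0.25, N = 250L, fs = 26),
    gyro  = list(m = 5L, r = 0.40, N = 750L, fs = 52.6),
    tilt  = list(m = 3L, r = 0.35, N = 250L, fs = 52.6))
  p <- list(signal = signal,
            m = if (is.null(m)) def$m else as.integer(m),
            r = if (is.null(r)) def$r else r,
            N = if (is.null(N)) def$N else as.integer(N),
            fs = if (is.null(fs)) def$fs else fs)
  if (p$m < 1) stop("m must be >= 1")
  if (p$r <= 0) stop("r must be positive")
  if (p$N <= p$m + 1) stop("N must exceed m + 1")
  structure(p, class = "SampEnParams")
}

# decimation factor: analysis rate must be the native rate divided by a
# power of two (52.6 -> 26.3 ~ 26 -> 13.15 ~ 13)
.decimationFactor <- function(nativeFs, fs) {
  k <- nativeFs / fs
  k2 <- 2^round(log2(k))
  if (abs(k2 / k - 1) > 0.06)
    stop("analysis rate must divide the native rate by a power of two")
  as.integer(k2)
}

#' Windowed Sample Entropy of an active-masked signal
#'
#' Decimates each contiguous active segment to the analysis rate (keeping
#' every k-th sample), splits it into non-overlapping windows of `N`
#' samples (remainders discarded), computes Sample Entropy per window with
#' tolerance `r` x SD(window), and aggregates the defined window entropies
#' by their arithmetic mean into one subject-level value.
#'
#' @param x list of numeric vectors (one per contiguous active segment), or
#'   a single numeric vector, or a numeric vector plus a logical `mask`
#'   whose `TRUE` runs define the segments.
#' @param params a [sampEnParams()] list.
#' @param nativeFs native sampling rate, Hz.
#' @param mask optional logical mask (with vector `x`).
#' @return a [SampEnResult-class].
#' @export
sampEnSignal <- function(x, params, nativeFs = 52.6, mask = NULL) {
  stopifnot(inherits(params, "SampEnParams"))
  if (!is.list(x)) {
    segs <- if (is.null(mask)) list(as.numeric(x)) else {
      sm <- .maskSegments(mask)
      apply(sm, 1, function(s) x[s[1]:(s[2] - 1)], simplify = FALSE)
    }
  } else segs <- x
  k <- .decimationFactor(nativeFs, params$fs)
  vals <- numeric(0)
  for (s in segs) {
    d <- s[seq(1, length(s), by = k)]
    if (length(d) < params$N) next
    vals <- c(vals, sampen_windows_cpp(d, params$m, params$r, params$N))
  }
  used <- sum(!is.na(vals))
  new("SampEnResult",
      values = vals,
      subjectValue = if (used > 0) mean(vals, na.rm = TRUE) else NA_real_,
      nSegmentsUsed = as.integer(used),
      nSegmentsUndefined = as.integer(sum(is.na(vals))),
      params = unclass(params))
}

#' Sample Entropy parameter grid search
#'
#' Evaluates every combination of the supplied parameter grids on a cohort
#' of signals, computing each subject's aggregate entropy and its Pearson
#' correlation with the UEFM score, and returns the combination maximizing
#' the correlation together with the full table.
#'
#' @param signals list (one element per subject) of segment lists or
#'   numeric vectors, as accepted by [sampEnSignal()].
#' @param uefmScores numeric, one per subject.
#' @param signal signal kind for the defaults (`"accel"`, `"gyro"`,
#'   `"tilt"`).
#' @param mGrid,rGrid,NGrid,fsGrid candidate values; defaults are the
#'   per-signal reference values (singleton grids).
#' @param nativeFs native sampling rate, Hz.
#' @return list with `best` (a `SampEnParams`) and `table` (data.frame
#'   `m`, `r`, `N`, `fs`, `r_uefm`, `p`, `nDefined`). Combinations whose
#'   entropy is undefined for every subject are kept in the table with
#'   `NA` correlation and skipped for selection.
#' @export
sampEnGridSearch <- function(signals, uefmScores,
                             signal = c("accel", "gyro", "tilt"),
                             mGrid = NULL, rGrid = NULL, NGrid = NULL,
                             fsGrid = NULL, nativeFs = 52.6) {
  signal <- match.arg(signal)
  if (length(signals) < 3) stop("grid search needs at least 3 subjects")
  if (sd(uefmScores) == 0) stop("UEFM scores have zero variance")
  def <- sampEnParams(signal)
  grid <- expand.grid(m = if (is.null(mGrid)) def$m else mGrid,
                      r = if (is.null(rGrid)) def$r else rGrid,
                      N = if (is.null(NGrid)) def$N else NGrid,
                      fs = if (is.null(fsGrid)) def$fs else fsGrid)
  grid$r_uefm <- NA_real_
  grid$p <- NA_real_
  grid$nDefined <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    p <- sampEnParams(signal, m = grid$m[i], r = grid$r[i],
                      N = grid$N[i], fs = grid$fs[i])
    v <- vapply(signals, function(s)
      subjectValue(sampEnSignal(s, p, nativeFs = nativeFs)), 0)
    ok <- !is.na(v)
    grid$nDefined[i] <- sum(ok)
    if (sum(ok) >= 3 && sd(v[ok]) > 0 && sd(uefmScores[ok]) > 0) {
      ct <- cor.test(v[ok], uefmScores[ok])
      grid$r_uefm[i] <- unname(ct$estimate)
      grid$p[i] <- ct$p.value
    }
  }
  if (all(is.na(grid$r_uefm))) stop("no parameter combination gave a defined correlation")
  bi <- which.max(grid$r_uefm)
  list(best = sampEnParams(signal, m = grid$m[bi], r = grid$r[bi],
                           N = grid$N[bi], fs = grid$fs[bi]),
       table = grid)
}
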