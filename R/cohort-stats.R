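# Cohort-level statistics: groups, per-feature tests, VIF, backward
# elimination.

#' Assign impairment groups from UEFM scores
#'
#' Group 1 (severe, no hand function): UEFM < 30. Group 2 (moderate, hand
#' function but low daily hand use): 30 <= UEFM < 50. Group 3 (mild,
#' regular hand use): UEFM >= 50.
#'
#' @param uefmScores numeric scores in `[0, 66]`.
#' @return integer vector of groups 1/2/3.
#' @examples
#' assignGroups(c(29, 30, 49, 50, 66))
#' @export
assignGroups <- function(uefmScores) {
  if (any(uefmScores < 0 | uefmScores > 66, na.rm = TRUE))
    stop("UEFM scores must lie in [0, 66]")
  ifelse(uefmScores < 30, 1L, ifelse(uefmScores < 50, 2L, 3L))
}

#' Cohen's D with pooled SD
#'
#' `(mean(x) - mean(y)) / s_pooled` with the classic pooled standard
#' deviation. Antisymmetric under swapping the groups; callers that follow
#' the reporting convention pass the less-impaired side as `x`.
#'
#' @param x,y numeric samples from the two groups.
#' @return signed effect size.
#' @export
cohenD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

# unpaired two-sample t-test (pooled variance, matching the pooled-SD D)
.contrast <- function(values, groups, lower, higher) {
  a <- values[groups %in% higher]   # less impaired side
  b <- values[groups %in% lower]    # more impaired side
  if (length(a) < 2 || length(b) < 2)
    return(c(d = NA_real_, p = NA_real_))
  c(d = cohenD(a, b),
    p = t.test(a, b, var.equal = TRUE)$p.value)
}

#' Per-feature association with impairment
#'
#' For every feature: simple linear regression against the UEFM score
#' (Pearson r, its p-value, R^2), one-way ANOVA across the three
#' impairment groups (F, p), and unpaired pooled-variance t-tests with
#' Cohen's D for the four group contrasts (1 vs 2, 2 vs 3, 1 vs 2+3,
#' 1+2 vs 3; D signed as less-impaired minus more-impaired side).
#' Non-finite feature values (e.g. a flagged ratio with an empty
#' denominator bin) are excluded per feature.
#'
#' @param x a [QOMEExperiment-class], or a features x subjects matrix.
#' @param uefmScores,groups needed when `x` is a matrix; groups default to
#'   [assignGroups()] of the scores.
#' @return data.frame with one row per feature: `feature`, `pearson_r`,
#'   `p`, `r_squared`, `d_1v2`, `p_1v2`, `d_2v3`, `p_2v3`, `d_1v23`,
#'   `p_1v23`, `d_12v3`, `p_12v3`, `anova_f`, `anova_p`.
#' @export
featureStatTable <- function(x, uefmScores = NULL, groups = NULL) {
  if (is(x, "QOMEExperiment")) {
    fmat <- featureMatrix(x)
    uefmScores <- uefm(x)
    groups <- SummarizedExperiment::colData(x)$group
  } else fmat <- as.matrix(x)
  stopifnot(!is.null(uefmScores), ncol(fmat) == length(uefmScores))
  if (is.null(groups)) groups <- assignGroups(uefmScores)
  rows <- lapply(rownames(fmat), function(fn) {
    v <- fmat[fn, ]
    ok <- is.finite(v)
    vv <- v[ok]; uu <- uefmScores[ok]; gg <- groups[ok]
    if (length(vv) < 4 || sd(vv) == 0) {
      ct <- list(estimate = NA_real_, p.value = NA_real_)
    } else ct <- cor.test(vv, uu)
    c12 <- .contrast(vv, gg, lower = 1, higher = 2)
    c23 <- .contrast(vv, gg, lower = 2, higher = 3)
    c1v23 <- .contrast(vv, gg, lower = 1, higher = c(2, 3))
    c12v3 <- .contrast(vv, gg, lower = c(1, 2), higher = 3)
    if (length(unique(gg)) >= 2 && sd(vv) > 0) {
      an <- stats::anova(lm(vv ~ factor(gg)))
      aF <- an$`F value`[1]; aP <- an$`Pr(>F)`[1]
    } else { aF <- NA_real_; aP <- NA_real_ }
    data.frame(feature = fn,
               pearson_r = unname(ct$estimate), p = ct$p.value,
               r_squared = unname(ct$estimate)^2,
               d_1v2 = c12["d"], p_1v2 = c12["p"],
               d_2v3 = c23["d"], p_2v3 = c23["p"],
               d_1v23 = c1v23["d"], p_1v23 = c1v23["p"],
               d_12v3 = c12v3["d"], p_12v3 = c12v3["p"],
               anova_f = aF, anova_p = aP,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R_i^2)` where `R_i^2` comes from regressing variable i
#' on all the others. Values at or above 5 flag problematic
#' multicollinearity; perfect collinearity yields an `Inf` sentinel.
#'
#' @param x numeric matrix or data.frame, observations x variables
#'   (>= 2 variables, more observations than variables).
#' @return named numeric vector of VIFs with attribute `flagged` (logical,
#'   `VIF >= 5`).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("VIF needs at least 2 variables")
  if (nrow(x) <= p) stop("VIF needs more observations than variables")
  out <- vapply(seq_len(p), function(i) {
    fit <- lm(x[, i] ~ x[, -i, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(x)
  attr(out, "flagged") <- out >= 5
  out
}

#' Backward elimination with AIC model selection
#'
#' Predicts the UEFM score from the feature matrix by ordinary least
#' squares. Variables whose simple correlation with the score is not
#' significant (two-sided, `p >= prefilterAlpha`) are dropped first; the
#' remaining model is then reduced one variable at a time, removing the
#' coefficient with the highest t-test p-value, down to a single variable.
#' Every step's model is scored with the Gaussian maximum-likelihood AIC
#' `2k - 2 ln L` (k counting the intercept, the slopes and the residual
#' variance), and the minimum-AIC model is selected; steps with
#' `delta = AIC - min(AIC) < 2` have substantial empirical support.
#'
#' @param x observations x variables matrix (or data.frame), or a
#'   [QOMEExperiment-class] (its feature matrix is transposed internally
#'   and the `inactive_fraction` row, being the filter's own output rather
#'   than a Table-style feature, is excluded).
#' @param y numeric response (UEFM scores); taken from the experiment when
#'   `x` is a [QOMEExperiment-class].
#' @param prefilterAlpha significance level of the correlation prefilter.
#' @return list of class `EliminationTrace`: `steps` (data.frame `step`,
#'   `nVariables`, `variables`, `removed`, `maxP`, `aic`, `delta`,
#'   `supported`), `selected` (character vector of the minimum-AIC model's
#'   variables), `selectedFit` (the `lm`), `prefilterDropped`.
#' @export
backwardEliminate <- function(x, y = NULL, prefilterAlpha = 0.05) {
  if (is(x, "QOMEExperiment")) {
    y <- uefm(x)
    fm <- featureMatrix(x)
    x <- t(fm[setdiff(rownames(fm), "inactive_fraction"), , drop = FALSE])
  }
  x <- as.data.frame(x)
  stopifnot(!is.null(y), nrow(x) == length(y))
  ok <- rowSums(!is.finite(as.matrix(x))) == 0 & is.finite(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]

  pcor <- vapply(x, function(v)
    if (sd(v) == 0) 1 else cor.test(v, y)$p.value, 0)
  dropped <- names(pcor)[pcor >= prefilterAlpha]
  vars <- setdiff(colnames(x), dropped)
  if (length(vars) < 1) stop("no variable survives the correlation prefilter")
  if (nrow(x) <= length(vars) + 1)
    stop("need more observations than initial variables + 1")

  steps <- list()
  fits <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    df <- data.frame(y = y, x[, vars, drop = FALSE])
    fit <- lm(y ~ ., data = df)
    k <- length(coef(fit)) + 1          # slopes + intercept + sigma^2
    aic <- 2 * k - 2 * as.numeric(logLik(fit))
    ps <- summary(fit)$coefficients[-1, 4]
    names(ps) <- vars
    worst <- names(ps)[which.max(ps)]
    steps[[step]] <- data.frame(
      step = step, nVariables = length(vars),
      variables = paste(vars, collapse = "+"),
      removed = if (length(vars) > 1) worst else NA_character_,
      maxP = max(ps), aic = aic)
    fits[[step]] <- fit
    if (length(vars) == 1) break
    vars <- setdiff(vars, worst)
  }
  tab <- do.call(rbind, steps)
  tab$delta <- tab$aic - min(tab$aic)
  tab$supported <- tab$delta < 2
  best <- which.min(tab$aic)
  structure(list(steps = tab,
                 selected = strsplit(tab$variables[best], "+", fixed = TRUE)[[1]],
                 selectedFit = fits[[best]],
                 prefilterDropped = dropped),
            class = "EliminationTrace")
}

#' @export
print.EliminationTrace <- function(x, ...) {
  cat("Backward elimination (", nrow(x$steps), " steps)\n", sep = "")
  if (length(x$prefilterDropped))
    cat("  prefilter dropped:", paste(x$prefilterDropped, collapse = ", "), "\n")
  print(x$steps[, c("step", "nVariables", "removed", "maxP", "aic", "delta")],
        row.names = FALSE, digits = 4)
  cat("  selected:", paste(x$selected, collapse = " + "), "\n")
  invisible(x)
}
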