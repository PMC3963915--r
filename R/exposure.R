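#' Substitute values below the limit of detection
#'
#' Replaces every censored measurement by half the limit of detection, the
#' standard substitution for biomonitoring data with a small censored
#' fraction. By default a value is treated as censored when it is missing or
#' strictly below `lod`; an explicit logical `censored` flag (as carried by
#' the cohort table's `*_below_lod` columns) overrides that rule. The
#' operation is idempotent: `lod/2` is itself below `lod`, so re-imputation
#' leaves values unchanged.
#'
#' @param values numeric concentrations (ug/L); censored entries may be NA.
#' @param lod limit of detection (ug/L, positive).
#' @param censored optional logical vector flagging censored entries.
#' @return numeric vector of the same length with censored entries set to
#'   `lod/2`.
#' @examples
#' imputeBelowLOD(c(0.5, NA, 0.01), lod = 0.028)
#' @export
imputeBelowLOD <- function(values, lod, censored = NULL) {
  if (!is.numeric(lod) || length(lod) != 1L || is.na(lod) || lod <= 0)
    stop("lod must be a single positive number")
  if (is.null(censored)) censored <- is.na(values) | values < lod
  stopifnot(length(censored) == length(values))
  if (any(!is.na(values) & values < 0 & !censored))
    stop("negative uncensored concentrations")
  values[censored] <- lod / 2
  values
}

#' Classify arsenic exposure into extreme groups on the log scale
#'
#' Computes the geometric mean and the multiplicative (ln-scale, n-1
#' denominator) standard deviation and labels each subject `low` when its
#' value lies strictly below `geomean / exp(sd(ln))`, `high` when strictly
#' above `geomean * exp(sd(ln))`, and `median` otherwise (boundary ties are
#' `median`). "Geometric mean plus standard deviation" is read
#' multiplicatively: an arithmetic reading is inconsistent with a positive
#' lower threshold for right-skewed exposures. The interquartile range uses
#' type-7 (linear interpolation) quantiles.
#'
#' @param values positive concentrations (ug/L), already LOD-imputed.
#' @return an [ExposureClassing-class].
#' @examples
#' cls <- classifyExposure(rlnorm(100, log(0.56), log(3.25)))
#' table(exposureLabels(cls))
#' @export
classifyExposure <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (anyNA(values) || any(values <= 0))
    stop("all values must be positive (impute below-LOD entries first)")
  lv <- log(values)
  m <- mean(lv)
  s <- sd(lv)
  lo <- exp(m - s)
  hi <- exp(m + s)
  labels <- factor(ifelse(values < lo, "low",
                          ifelse(values > hi, "high", "median")),
                   levels = c("low", "median", "high"))
  new("ExposureClassing",
      labels = labels,
      lowThreshold = lo,
      highThreshold = hi,
      geomean = exp(m),
      logSD = s,
      iqr = unname(quantile(values, 0.75, type = 7) -
                     quantile(values, 0.25, type = 7)))
}

#' @describeIn classifyExposure per-subject low/median/high labels.
#' @param object an [ExposureClassing-class].
#' @export
setMethod("exposureLabels", "ExposureClassing", function(object) object@labels)

#' @describeIn classifyExposure the dichotomous collapse used by the
#'   mediation cascade: `high` versus `medianOrLow`.
#' @export
setMethod("highVsRest", "ExposureClassing", function(object) {
  factor(ifelse(object@labels == "high", "high", "medianOrLow"),
         levels = c("medianOrLow", "high"))
})

setMethod("show", "ExposureClassing", function(object) {
  n <- table(object@labels)
  cat("ExposureClassing of", length(object@labels), "subjects\n")
  cat(sprintf("  geometric mean %.3g ug/L, ln-scale SD %.3f\n",
              object@geomean, object@logSD))
  cat(sprintf("  thresholds: low < %.3g, high > %.3g ug/L\n",
              object@lowThreshold, object@highThreshold))
  cat(sprintf("  counts: low %d / median %d / high %d; IQR %.3g ug/L\n",
              n[["low"]], n[["median"]], n[["high"]], object@iqr))
  invisible(object)
})

#' Pearson correlation of two exposures on the natural-log scale
#'
#' Drops pairs with a missing member, ln-transforms both series, and returns
#' the Pearson correlation with the usual t-transform two-sided p-value on
#' n - 2 degrees of freedom.
#'
#' @param x,y paired positive concentrations; entries may be NA.
#' @return list with `r`, `p`, `n` (pairs used) and `nDropped`.
#' @export
logPearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (any(c(x[ok], y[ok]) <= 0)) stop("values must be positive")
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 complete pairs")
  ct <- cor.test(log(x[ok]), log(y[ok]), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       nDropped = sum(!ok))
}
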