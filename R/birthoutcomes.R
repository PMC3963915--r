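#' Classify newborns as small for gestational age
#'
#' A newborn is SGA when its birth weight lies strictly below the sex-specific
#' 10th percentile for its completed gestational week. Curves are per
#' completed week; a missing (sex, week) entry is an explicit error rather
#' than an interpolation.
#'
#' @param bw birth weights (g).
#' @param ga completed gestational weeks.
#' @param sex factor or character matching the `sex` column of `curves`.
#' @param curves data.frame with columns `sex`, `week`, `p10_g`, e.g. from
#'   [generateReferenceCurves()] or [readGrowthCurves()].
#' @return logical vector (NA where bw or ga is missing).
#' @examples
#' curves <- data.frame(sex = "girls", week = 40, p10_g = 2800)
#' classifySGA(c(2700, 2800), c(40, 40), c("girls", "girls"), curves)
#' @export
classifySGA <- function(bw, ga, sex, curves) {
  stopifnot(all(c("sex", "week", "p10_g") %in% names(curves)))
  n <- length(bw)
  stopifnot(length(ga) == n, length(sex) == n)
  key <- paste(as.character(sex), ga)
  ckey <- paste(as.character(curves$sex), curves$week)
  if (anyDuplicated(ckey)) stop("duplicate (sex, week) entries in curves")
  idx <- match(key, ckey)
  known <- !is.na(bw) & !is.na(ga)
  if (any(known & is.na(idx)))
    stop("missing growth-curve entry for: ",
         paste(unique(key[known & is.na(idx)]), collapse = ", "))
  out <- bw < curves$p10_g[idx]
  out[!known] <- NA
  out
}

#' Gestational-age adjustment of birth weight and extreme groups
#'
#' Fits, separately by sex, an ordinary least squares model of birth weight
#' on gestational age with a quadratic term, and derives per subject the
#' expected weight, the observed/expected ratio and its natural log. Extreme
#' groups are labelled within sex at the arithmetic mean plus or minus one SD
#' of the ln ratio: `low` below, `high` above, `mid` otherwise. Subjects with
#' missing birth weight or gestational age are excluded from fitting and
#' labelled NA, with the count recorded.
#'
#' @param cohort data.frame with the model columns.
#' @param bw,ga,sex names of the birth weight, gestational age and sex
#'   columns.
#' @return a [GAAdjustment-class].
#' @examples
#' sim <- generateCohort(simConfig(nSubjects = 60, seed = 3))
#' adj <- fitGAAdjustment(sim$cohort)
#' table(bwExtremes(adj), useNA = "ifany")
#' @export
fitGAAdjustment <- function(cohort, bw = "birth_weight_g", ga = "ga_weeks",
                            sex = "sex") {
  stopifnot(all(c(bw, ga, sex) %in% names(cohort)))
  w <- cohort[[bw]]
  g <- cohort[[ga]]
  sx <- as.character(cohort[[sex]])
  ok <- !is.na(w) & !is.na(g)
  n <- nrow(cohort)
  expected <- ratio <- lnRatio <- rep(NA_real_, n)
  extreme <- factor(rep(NA_character_, n), levels = c("low", "mid", "high"))
  coefs <- list()
  thresholds <- list()
  for (s in sort(unique(sx))) {
    i <- which(sx == s & ok)
    if (length(i) < 6L) stop("fewer than 6 usable subjects for sex ", s)
    if (length(unique(g[i])) < 3L)
      stop("singular design: fewer than 3 distinct gestational ages for sex ",
           s)
    fit <- lm(w[i] ~ g[i] + I(g[i]^2))
    co <- unname(coef(fit))
    coefs[[s]] <- c(intercept = co[1], ga = co[2], ga2 = co[3])
    expected[i] <- co[1] + co[2] * g[i] + co[3] * g[i]^2
    ratio[i] <- w[i] / expected[i]
    if (any(ratio[i] <= 0))
      stop("non-positive observed/expected ratio for sex ", s)
    lnRatio[i] <- log(ratio[i])
    m <- mean(lnRatio[i])
    sdev <- sd(lnRatio[i])
    thresholds[[s]] <- c(low = m - sdev, high = m + sdev)
    if (sdev < 1e-12) {
      # degenerate (noise-free) fit: numerical fuzz must not create extremes
      extreme[i] <- "mid"
    } else {
      extreme[i] <- ifelse(lnRatio[i] < m - sdev, "low",
                           ifelse(lnRatio[i] > m + sdev, "high", "mid"))
    }
  }
  tab <- data.frame(sex = sx, expected_g = expected, ratio = ratio,
                    ln_ratio = lnRatio, extreme = extreme,
                    stringsAsFactors = FALSE)
  if ("subject_id" %in% names(cohort)) rownames(tab) <- cohort$subject_id
  new("GAAdjustment", table = tab, coefficients = coefs,
      thresholds = thresholds, nMissing = sum(!ok))
}

#' @describeIn fitGAAdjustment per-subject extreme labels (factor
#'   low/mid/high; NA for excluded subjects).
#' @param object a [GAAdjustment-class].
#' @export
setMethod("bwExtremes", "GAAdjustment", function(object)
  object@table$extreme)

setMethod("show", "GAAdjustment", function(object) {
  cat("GAAdjustment over", nrow(object@table), "subjects (",
      object@nMissing, "excluded for missing data )\n")
  for (s in names(object@coefficients)) {
    co <- object@coefficients[[s]]
    cat(sprintf("  %s: expected BW = %.1f + %.1f GA + %.3f GA^2\n",
                s, co["intercept"], co["ga"], co["ga2"]))
  }
  print(table(object@table$sex, object@table$extreme))
  invisible(object)
})
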