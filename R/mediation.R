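# Baron-Kenny four-model mediation cascade for a transcript between
# dichotomized arsenic exposure and birth weight.

coefRow <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) stop("term '", term, "' missing from fit")
  b <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  crit <- qt(0.975, fit$df.residual)
  c(beta = unname(b), ci_low = unname(b - crit * se),
    ci_high = unname(b + crit * se), p = unname(sm[term, "Pr(>|t|)"]))
}

#' Run the Baron-Kenny mediation cascade for one transcript
#'
#' Tests a gene's log2 expression as mediator between dichotomized arsenic
#' exposure (high versus median-or-low) and birth weight with four linear
#' models:
#'
#' 1. birth weight on exposure, adjusted for sex, gestational age, smoking
#'    and parity;
#' 2. mediator expression on exposure, adjusted for sex and gestational age;
#' 3. birth weight on the mediator, adjusted as in model 1;
#' 4. birth weight on mediator and exposure jointly, adjusted as in model 1.
#'
#' The sex-by-mediator cross-product is screened at p < 0.20 in model 3 and,
#' when flagged, enters models 3 and 4, whose mediator effects are then
#' reported per sex. The mediator stays continuous on the log2 scale, so its
#' coefficient reads as grams per doubling of expression. Mediation requires
#' all four exposure/mediator coefficients significant at `alpha` (for
#' sex-specific models, in at least one stratum); the verdict is "full" when
#' the model-4 exposure effect additionally loses significance, "partial"
#' when it is attenuated in magnitude but still significant, and "none"
#' otherwise.
#'
#' @param cohort data.frame with columns `birth_weight_g`, `sex`, `ga_weeks`,
#'   `smoking`, `parity`, and (when `asHigh` is not supplied) `as_cord_ugL`
#'   plus `as_cord_below_lod`.
#' @param mediator numeric log2 expression, one value per cohort row.
#' @param asHigh optional factor with levels medianOrLow/high; by default
#'   derived via [imputeBelowLOD()], [classifyExposure()] and
#'   [highVsRest()] from the cohort's cord arsenic, with the limit of
#'   detection in `lod`.
#' @param lod limit of detection used for the default exposure derivation.
#' @param alpha significance level for the mediation requirements.
#' @param interactionThreshold screening threshold for the sex-by-mediator
#'   cross-product.
#' @param extraCovariates additional cohort columns entered into every model
#'   (used by [sensitivityAnalysis()]).
#' @param subset optional logical vector of cohort rows to analyze.
#' @return a [MediationResult-class].
#' @export
runBaronKenny <- function(cohort, mediator, asHigh = NULL, lod = 0.028,
                          alpha = 0.05, interactionThreshold = 0.20,
                          extraCovariates = character(), subset = NULL) {
  stopifnot(length(mediator) == nrow(cohort))
  if (is.null(asHigh)) {
    vals <- imputeBelowLOD(cohort$as_cord_ugL, lod,
                           censored = cohort$as_cord_below_lod)
    asHigh <- highVsRest(classifyExposure(vals))
  }
  stopifnot(length(asHigh) == nrow(cohort))
  d <- data.frame(bw = cohort$birth_weight_g,
                  as_group = asHigh,
                  sex = cohort$sex,
                  ga = cohort$ga_weeks,
                  smoking = cohort$smoking,
                  parity = cohort$parity,
                  mediator = mediator)
  for (v in extraCovariates) d[[v]] <- cohort[[v]]
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  if (!any(d$as_group == "high", na.rm = TRUE))
    stop("high-exposure group is empty")
  if (length(unique(d$mediator[!is.na(d$mediator)])) < 2L)
    stop("expression column is constant")

  fullAdj <- c("sex", "ga", "smoking", "parity", extraCovariates)
  asTerm <- "as_grouphigh"

  cc <- function(vars) d[complete.cases(d[vars]), , drop = FALSE]

  d1 <- cc(c("bw", "as_group", fullAdj))
  m1 <- lm(stats::reformulate(c("as_group", fullAdj), "bw"), data = d1)
  r1 <- coefRow(m1, asTerm)

  d2 <- cc(c("mediator", "as_group", "sex", "ga", extraCovariates))
  m2 <- lm(stats::reformulate(c("as_group", "sex", "ga", extraCovariates),
                              "mediator"), data = d2)
  r2 <- coefRow(m2, asTerm)

  d3 <- cc(c("bw", "mediator", fullAdj))
  m3std <- lm(stats::reformulate(c("mediator", fullAdj, "mediator:sex"), "bw"),
              data = d3)
  dr <- drop1(m3std, scope = ~ mediator:sex, test = "F")
  interactionP <- dr[["Pr(>F)"]][2]
  includeInt <- is.finite(interactionP) && interactionP < interactionThreshold

  sexLevels <- levels(droplevels(d3$sex))
  fitMediatorModel <- function(dd, withAs) {
    base <- c(fullAdj, if (withAs) "as_group")
    if (includeInt) {
      # sex-specific slopes parameterization: sex + sex:mediator
      f <- stats::reformulate(c(base, "sex:mediator"), "bw")
      fit <- lm(f, data = dd)
      rows <- lapply(sexLevels, function(s) {
        term <- paste0("sex", s, ":mediator")
        c(stratum = s, as.list(coefRow(fit, term)))
      })
    } else {
      f <- stats::reformulate(c("mediator", base), "bw")
      fit <- lm(f, data = dd)
      rows <- list(c(stratum = "all", as.list(coefRow(fit, "mediator"))))
    }
    list(fit = fit, rows = rows)
  }

  f3 <- fitMediatorModel(d3, withAs = FALSE)
  d4 <- cc(c("bw", "mediator", "as_group", fullAdj))
  f4 <- fitMediatorModel(d4, withAs = TRUE)
  r4as <- coefRow(f4$fit, asTerm)

  sigAny <- function(rows) any(vapply(rows, function(r) r$p < alpha, logical(1)))
  requirements <- c(
    exposure_outcome = unname(r1["p"] < alpha),
    exposure_mediator = unname(r2["p"] < alpha),
    mediator_outcome = sigAny(f3$rows),
    mediator_outcome_adjusted = sigAny(f4$rows)
  )
  beta1 <- r1[["beta"]]
  beta4 <- r4as[["beta"]]
  verdict <- "none"
  if (all(requirements)) {
    if (r4as[["p"]] >= alpha) verdict <- "full"
    else if (abs(beta4) < abs(beta1)) verdict <- "partial"
  }

  rowDf <- function(model, predictor, stratum, v)
    data.frame(model = model, predictor = predictor, stratum = stratum,
               beta = v[["beta"]], ci_low = v[["ci_low"]],
               ci_high = v[["ci_high"]], p = v[["p"]],
               stringsAsFactors = FALSE)
  medRows <- function(model, rows)
    do.call(rbind, lapply(rows, function(r)
      rowDf(model, "mediator", r$stratum,
            c(beta = r$beta, ci_low = r$ci_low, ci_high = r$ci_high,
              p = r$p))))
  tab <- rbind(
    rowDf("model1", "as_high", "all", r1),
    rowDf("model2", "as_high", "all", r2),
    medRows("model3", f3$rows),
    medRows("model4", f4$rows),
    rowDf("model4", "as_high", "all", r4as)
  )

  new("MediationResult",
      verdict = verdict,
      requirements = requirements,
      table = tab,
      attenuation = beta1 - beta4,
      interactionP = unname(interactionP),
      interactionIncluded = includeInt,
      alpha = alpha,
      nPerModel = c(model1 = nrow(d1), model2 = nrow(d2),
                    model3 = nrow(d3), model4 = nrow(d4)),
      models = list(model1 = m1, model2 = m2, model3 = f3$fit,
                    model4 = f4$fit))
}

#' @describeIn runBaronKenny the mediation verdict ("none", "partial" or
#'   "full").
#' @param object a [MediationResult-class].
#' @export
setMethod("verdict", "MediationResult", function(object) object@verdict)

#' @describeIn runBaronKenny the per-model coefficient table.
#' @export
setMethod("mediationTable", "MediationResult", function(object) object@table)

#' @describeIn runBaronKenny named logical vector of the four mediation
#'   requirements, so failed steps are visible rather than silent.
#' @export
setMethod("requirementsMet", "MediationResult", function(object)
  object@requirements)

setMethod("show", "MediationResult", function(object) {
  cat("Baron-Kenny mediation cascade\n")
  cat("  verdict:", object@verdict, "\n")
  cat("  requirements met:",
      paste(names(object@requirements)[object@requirements], collapse = ", "),
      "\n")
  failed <- names(object@requirements)[!object@requirements]
  if (length(failed)) cat("  requirements failed:",
                          paste(failed, collapse = ", "), "\n")
  cat(sprintf("  sex x mediator interaction: p = %.3g (%sincluded)\n",
              object@interactionP,
              if (object@interactionIncluded) "" else "not "))
  cat(sprintf("  attenuation of the exposure effect: %.1f g\n",
              object@attenuation))
  print(object@table, digits = 3)
  invisible(object)
})

#' Sensitivity analyses for a mediation cascade
#'
#' Refits all four Baron-Kenny models under the requested perturbations and
#' reports whether every significance conclusion (each coefficient's p < 0.05
#' flag, matched by model, predictor and stratum) is preserved:
#' `addBmi` adds maternal BMI to every model, `adjustComplications` adds the
#' pregnancy-complications indicator, and `excludeComplications` drops the
#' affected subjects. An empty option set returns the baseline untouched.
#'
#' @inheritParams runBaronKenny
#' @param options subset of `c("addBmi", "adjustComplications",
#'   "excludeComplications")`.
#' @return list with `baseline` (a [MediationResult-class]) and `comparisons`
#'   (data.frame with columns option, verdict, conclusionsPreserved).
#' @export
sensitivityAnalysis <- function(cohort, mediator, asHigh = NULL, lod = 0.028,
                                options = c("addBmi", "adjustComplications",
                                            "excludeComplications"), ...) {
  options <- unique(options)
  bad <- setdiff(options, c("addBmi", "adjustComplications",
                            "excludeComplications"))
  if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
  baseline <- runBaronKenny(cohort, mediator, asHigh = asHigh, lod = lod, ...)
  sigKey <- function(res) {
    tab <- mediationTable(res)
    setNames(tab$p < 0.05,
             paste(tab$model, tab$predictor, tab$stratum, sep = "|"))
  }
  base <- sigKey(baseline)
  rows <- lapply(options, function(opt) {
    res <- switch(opt,
      addBmi = runBaronKenny(cohort, mediator, asHigh = asHigh, lod = lod,
                             extraCovariates = "maternal_bmi", ...),
      adjustComplications = runBaronKenny(cohort, mediator, asHigh = asHigh,
                                          lod = lod,
                                          extraCovariates = "complications",
                                          ...),
      excludeComplications = runBaronKenny(cohort, mediator, asHigh = asHigh,
                                           lod = lod,
                                           subset = cohort$complications == 0,
                                           ...))
    other <- sigKey(res)
    shared <- intersect(names(base), names(other))
    data.frame(option = opt, verdict = verdict(res),
               conclusionsPreserved = identical(base[shared], other[shared]),
               stringsAsFactors = FALSE)
  })
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(option = character(), verdict = character(),
               conclusionsPreserved = logical(), stringsAsFactors = FALSE)
  list(baseline = baseline, comparisons = comparisons)
}
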