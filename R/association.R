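# Exposure-outcome regression workflow: covariate selection, IQR-scaled
# effects, interaction testing and formal model diagnostics.

#' Backward covariate selection around forced confounders
#'
#' Operationalizes "covariates retained when significant at the 0.05 level"
#' as one-pass backward elimination from the full candidate model: fit the
#' outcome on the exposure, the forced confounders and all candidates, drop
#' the least significant candidate with p above `alpha` (multi-degree
#' candidates judged by their F or likelihood-ratio drop test), refit, and
#' repeat. Forced confounders and the exposure are never dropped. The drop
#' rule (largest p first) makes the result deterministic and independent of
#' candidate order.
#'
#' @param data data.frame.
#' @param outcome,exposure column names.
#' @param candidates character vector of candidate covariate columns.
#' @param forced covariates retained irrespective of significance (a priori
#'   confounders, e.g. sex and smoking).
#' @param alpha retention threshold (default 0.05).
#' @param family "gaussian" or "binomial".
#' @return character vector: forced covariates followed by retained
#'   candidates.
#' @export
selectCovariates <- function(data, outcome, exposure, candidates,
                             forced = c("sex", "smoking"), alpha = 0.05,
                             family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  vars <- unique(c(outcome, exposure, forced, candidates))
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  current <- candidates
  repeat {
    f <- stats::reformulate(c(exposure, forced, current), outcome)
    fit <- if (family == "gaussian") lm(f, data = d) else
      glm(f, data = d, family = binomial())
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop("singular design; aliased term(s): ", paste(bad, collapse = ", "))
    }
    if (!length(current)) break
    dr <- drop1(fit, scope = stats::reformulate(current),
                test = if (family == "gaussian") "F" else "Chisq")
    pcol <- grep("^Pr\\(", names(dr), value = TRUE)
    p <- dr[[pcol]][-1]
    names(p) <- rownames(dr)[-1]
    worst <- names(p)[which.max(p)]
    if (p[[worst]] > alpha) current <- setdiff(current, worst) else break
  }
  c(forced, current)
}

#' Linear exposure effect per interquartile-range increase
#'
#' Ordinary least squares of the outcome on the continuous exposure and
#' covariates. The reported estimate is the exposure coefficient multiplied
#' by `iqr`, i.e. the outcome change per IQR increase, with the Wald
#' confidence interval scaled identically. When `diagnostics = TRUE`, formal
#' model checks are run ([runDiagnostics()]) and the model is refitted
#' without the flagged influential subjects; both estimates are reported.
#'
#' @param data data.frame.
#' @param outcome,exposure column names (`exposure` must be numeric and
#'   non-constant).
#' @param covariates further adjustment columns.
#' @param iqr interquartile range used for scaling (exposure units).
#' @param diagnostics run formal diagnostics and the influential-subject
#'   refit (default TRUE).
#' @return an [EffectEstimate-class].
#' @export
fitLinearEffect <- function(data, outcome, exposure, covariates = character(),
                            iqr, diagnostics = TRUE) {
  stopifnot(is.numeric(iqr), length(iqr) == 1L, iqr > 0)
  vars <- unique(c(outcome, exposure, covariates))
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) < length(vars) + 5L) stop("too few complete cases")
  if (length(unique(d[[exposure]])) < 2L)
    stop("exposure '", exposure, "' is constant in the complete cases")
  f <- stats::reformulate(c(exposure, covariates), outcome)
  fit <- lm(f, data = d)
  if (anyNA(coef(fit))) stop("singular design")
  sm <- summary(fit)$coefficients
  b <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  crit <- qt(0.975, fit$df.residual)
  diag <- list()
  refit <- NA_real_
  if (diagnostics) {
    diag <- runDiagnostics(fit)
    keep <- setdiff(seq_len(nrow(d)), diag$influential)
    refitFit <- lm(f, data = d[keep, , drop = FALSE])
    refit <- unname(coef(refitFit)[exposure] * iqr)
  }
  new("EffectEstimate",
      outcome = outcome, exposure = exposure, family = "gaussian",
      estimate = unname(b * iqr),
      ciLow = unname((b - crit * se) * iqr),
      ciHigh = unname((b + crit * se) * iqr),
      p = unname(sm[exposure, "Pr(>|t|)"]),
      n = nrow(d), iqr = iqr,
      covariates = as.character(covariates),
      diagnostics = diag, refitEstimate = refit)
}

#' Logistic exposure effect as an odds ratio per IQR increase
#'
#' Maximum-likelihood logistic regression of a binary outcome on the
#' continuous exposure and covariates; the reported estimate is
#' `exp(coefficient * iqr)`, the odds multiplier per IQR increase, with the
#' Wald interval transformed identically. Perfect separation is reported as
#' an error rather than returned as a divergent estimate.
#'
#' @inheritParams fitLinearEffect
#' @return an [EffectEstimate-class] (`estimate` is an odds ratio).
#' @export
fitLogisticEffect <- function(data, outcome, exposure,
                              covariates = character(), iqr) {
  stopifnot(is.numeric(iqr), length(iqr) == 1L, iqr > 0)
  vars <- unique(c(outcome, exposure, covariates))
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y[!is.na(y)])) != 2L)
    stop("outcome must have both classes present")
  f <- stats::reformulate(c(exposure, covariates), outcome)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || max(abs(coef(fit)), na.rm = TRUE) > 20)
    stop("perfect (or quasi-perfect) separation in logistic fit")
  sm <- summary(fit)$coefficients
  b <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  crit <- qnorm(0.975)
  new("EffectEstimate",
      outcome = outcome, exposure = exposure, family = "binomial",
      estimate = unname(exp(b * iqr)),
      ciLow = unname(exp((b - crit * se) * iqr)),
      ciHigh = unname(exp((b + crit * se) * iqr)),
      p = unname(sm[exposure, "Pr(>|z|)"]),
      n = nrow(d), iqr = iqr,
      covariates = as.character(covariates),
      diagnostics = list(), refitEstimate = NA_real_)
}

setMethod("show", "EffectEstimate", function(object) {
  unit <- if (object@family == "binomial") "odds ratio" else "difference"
  cat(sprintf("EffectEstimate (%s): %s per IQR (%.3g) increase of %s\n",
              object@family, unit, object@iqr, object@exposure))
  cat(sprintf("  %s: %.4g (95%% CI %.4g, %.4g), p = %.3g, n = %d\n",
              object@outcome, object@estimate, object@ciLow, object@ciHigh,
              object@p, object@n))
  if (length(object@covariates))
    cat("  adjusted for:", paste(object@covariates, collapse = ", "), "\n")
  if (length(object@diagnostics)) {
    dg <- object@diagnostics
    cat(sprintf("  diagnostics: KS p = %.3g, White p = %.3g, lack-of-fit %s\n",
                dg$ksP, dg$whiteP,
                if (isTRUE(dg$lackOfFitApplicable))
                  sprintf("p = %.3g", dg$lackOfFitP) else "n/a"))
    cat(sprintf("  influential subjects: %d; refit estimate %.4g\n",
                length(dg$influential), object@refitEstimate))
  }
  invisible(object)
})

#' Cross-product interaction test at the 0.20 screening level
#'
#' Adds the `termA:termB` cross-product to the main-effects model and flags
#' interaction when its p-value falls below 0.20 (a deliberately liberal
#' screening threshold). When flagged, stratified fits by the categorical
#' term are returned so effect estimates can be reported per stratum.
#'
#' @param data data.frame.
#' @param outcome,termA,termB column names; `termB` is conventionally the
#'   stratification factor (e.g. sex).
#' @param covariates further adjustment columns.
#' @param family "gaussian" or "binomial".
#' @param threshold flag threshold (default 0.20).
#' @return list with `p`, `flagged`, and (when flagged) `stratified`: per
#'   stratum the coefficient row of `termA`.
#' @export
testInteraction <- function(data, outcome, termA, termB,
                            covariates = character(),
                            family = c("gaussian", "binomial"),
                            threshold = 0.20) {
  family <- match.arg(family)
  vars <- unique(c(outcome, termA, termB, covariates))
  stopifnot(all(vars %in% names(data)))
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  for (v in c(termA, termB))
    if (length(unique(d[[v]])) < 2L) stop("term '", v, "' is constant")
  cross <- paste0(termA, ":", termB)
  f <- stats::reformulate(c(termA, termB, covariates, cross), outcome)
  fit <- if (family == "gaussian") lm(f, data = d) else
    glm(f, data = d, family = binomial())
  if (anyNA(coef(fit))) stop("singular augmented design")
  dr <- drop1(fit, scope = stats::as.formula(paste("~", cross)),
              test = if (family == "gaussian") "F" else "Chisq")
  pcol <- grep("^Pr\\(", names(dr), value = TRUE)
  p <- dr[[pcol]][2]
  flagged <- is.finite(p) && p < threshold
  strat <- NULL
  if (flagged) {
    by <- d[[termB]]
    strat <- lapply(split(seq_len(nrow(d)), by), function(i) {
      sf <- stats::reformulate(c(termA, covariates), outcome)
      sfit <- if (family == "gaussian") lm(sf, data = d[i, ]) else
        glm(sf, data = d[i, ], family = binomial())
      sm <- summary(sfit)$coefficients
      row <- grep(paste0("^", termA), rownames(sm))
      sm[row, , drop = FALSE]
    })
  }
  list(p = unname(p), flagged = flagged, stratified = strat)
}

#' Formal diagnostics for a linear model
#'
#' Runs the standard assumption checks on a fitted `lm`:
#' Kolmogorov-Smirnov on the standardized residuals against the standard
#' normal; White's general heteroskedasticity test (the n R-squared LM
#' statistic from regressing squared residuals on the regressors, their
#' squares and pairwise cross-products); the classical pure-error lack-of-fit
#' F test, applicable only when predictor rows are replicated; and an
#' influence rule flagging subjects with leverage above `2p/n` or absolute
#' studentized residual above 3. Tests that cannot be computed degrade to NA
#' with an applicability flag, never to an error.
#'
#' @param fit an `lm` object.
#' @param leverageFactor multiplier of p/n in the leverage cutoff (default 2).
#' @param studentizedCutoff absolute studentized-residual cutoff (default 3).
#' @return list with `ksP`, `whiteP`, `whiteDf`, `lackOfFitP`,
#'   `lackOfFitApplicable`, and `influential` (row indices into the model
#'   frame).
#' @export
runDiagnostics <- function(fit, leverageFactor = 2, studentizedCutoff = 3) {
  stopifnot(inherits(fit, "lm"))
  n <- length(resid(fit))
  p <- fit$rank

  ksP <- tryCatch(
    suppressWarnings(ks.test(rstandard(fit), "pnorm")$p.value),
    error = function(e) NA_real_)

  white <- tryCatch(whiteTest(fit), error = function(e)
    list(p = NA_real_, df = NA_integer_))

  lof <- lackOfFitTest(fit)

  lev <- hatvalues(fit)
  stud <- rstudent(fit)
  influential <- which(lev > leverageFactor * p / n |
                         abs(stud) > studentizedCutoff)

  list(ksP = ksP, whiteP = white$p, whiteDf = white$df,
       lackOfFitP = lof$p, lackOfFitApplicable = lof$applicable,
       influential = unname(influential))
}

# White's general test via the studentized Breusch-Pagan LM statistic with
# the White auxiliary regressors (levels, squares, cross-products), pruned to
# full column rank.
whiteTest <- function(fit) {
  X <- model.matrix(fit)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!ncol(X)) stop("no regressors")
  aux <- X
  nonBinary <- apply(X, 2, function(v) length(unique(v)) > 2L)
  if (any(nonBinary)) aux <- cbind(aux, X[, nonBinary, drop = FALSE]^2)
  if (ncol(X) >= 2L) {
    cp <- utils::combn(ncol(X), 2L)
    aux <- cbind(aux, X[, cp[1, ], drop = FALSE] * X[, cp[2, ], drop = FALSE])
  }
  qrA <- qr(cbind(1, aux))
  keep <- qrA$pivot[seq_len(qrA$rank)]
  keep <- setdiff(keep, 1L) - 1L  # drop intercept, reindex into aux
  aux <- aux[, keep, drop = FALSE]
  colnames(aux) <- paste0("z", seq_len(ncol(aux)))
  df <- as.data.frame(aux)
  bp <- lmtest::bptest(fit, stats::reformulate(colnames(df)), data = df)
  list(p = unname(bp$p.value), df = unname(bp$parameter))
}

# Classical pure-error lack-of-fit F test; needs replicated predictor rows.
lackOfFitTest <- function(fit) {
  mf <- model.frame(fit)
  pred <- mf[, -1, drop = FALSE]
  y <- stats::model.response(mf)
  groups <- interaction(lapply(pred, as.character), drop = TRUE)
  c_ <- nlevels(groups)
  n <- length(y)
  p <- fit$rank
  if (c_ >= n || c_ <= p)
    return(list(p = NA_real_, applicable = FALSE))
  sspe <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
  sse <- sum(resid(fit)^2)
  sslf <- sse - sspe
  if (sspe <= 0) return(list(p = NA_real_, applicable = FALSE))
  fstat <- (sslf / (c_ - p)) / (sspe / (n - c_))
  list(p = pf(fstat, c_ - p, n - c_, lower.tail = FALSE), applicable = TRUE)
}
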