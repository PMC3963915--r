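#' @import methods
NULL

#' Simulation configuration for the synthetic mother-newborn cohort
#'
#' Parameters of the synthetic cohort generator. Construct with [simConfig()],
#' which supplies study-condition defaults: a cohort of 183 pairs, cord blood
#' arsenic lognormal with geometric mean 0.56 ug/L and multiplicative
#' geometric SD 3.25, limit of detection 0.028 ug/L, cord-maternal correlation
#' 0.82 on the natural-log scale, gestational age on completed weeks 34-42
#' with median 40, and birth weight effects of +216 g/week gestational age,
#' +161 g for boys, -111 g for maternal smoking, -184/-30 g for parity 0/1
#' versus 2+, and -47 g per interquartile-range increase of cord arsenic.
#' A planted mediator gene shifts by 0.30 log2 units in the high-arsenic
#' class and lowers birth weight by 182 g per doubling in girls.
#'
#' @slot nSubjects integer, number of mother-newborn pairs.
#' @slot asGeomean,asGSD geometric mean (ug/L) and multiplicative geometric SD
#'   of cord blood arsenic.
#' @slot asLOD assay limit of detection (ug/L).
#' @slot maternalCordLogCorr Pearson correlation of cord and maternal arsenic
#'   on the ln scale.
#' @slot gaWeeks,gaProbs support and probabilities of the completed-week
#'   gestational age distribution.
#' @slot bwIntercept,betaGA,betaSexBoys,betaSmoking,betaParity0,betaParity1
#'   birth weight linear predictor terms (g; parity contrasts vs 2+).
#' @slot betaAsPerIqr direct arsenic effect on birth weight, g per theoretical
#'   IQR of the latent exposure.
#' @slot betaAsHighGroup additional direct birth weight shift (g) for the
#'   high-arsenic class, used to plant dichotomous exposure effects.
#' @slot mediatorLog2FCHighAs planted mediator shift (log2 units) in the
#'   high-arsenic class.
#' @slot mediatorBwEffectGirls,mediatorBwEffectBoys mediator effect on birth
#'   weight, g per doubling of expression, by sex.
#' @slot mediatorBaseline baseline log2 expression of the mediator gene.
#' @slot nNullGenes number of null genes on the synthetic array.
#' @slot expressionNoiseSd per-subject biological SD of log2 expression.
#' @slot residualBwSd residual SD of birth weight (g).
#' @slot smokingPrev maternal smoking prevalence.
#' @slot parityProbs probabilities of parity categories 0, 1, 2+.
#' @slot unreliableRate fraction of array features carrying at least one
#'   failing reliability flag.
#' @slot qpcrNoiseSd technical SD of Cq values (cycles).
#' @slot seed integer seed, or NA to leave the RNG stream untouched.
#'
#' @seealso [simConfig()], [generateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer",
    asGeomean = "numeric",
    asGSD = "numeric",
    asLOD = "numeric",
    maternalCordLogCorr = "numeric",
    gaWeeks = "integer",
    gaProbs = "numeric",
    bwIntercept = "numeric",
    betaGA = "numeric",
    betaSexBoys = "numeric",
    betaSmoking = "numeric",
    betaParity0 = "numeric",
    betaParity1 = "numeric",
    betaAsPerIqr = "numeric",
    betaAsHighGroup = "numeric",
    mediatorLog2FCHighAs = "numeric",
    mediatorBwEffectGirls = "numeric",
    mediatorBwEffectBoys = "numeric",
    mediatorBaseline = "numeric",
    nNullGenes = "integer",
    expressionNoiseSd = "numeric",
    residualBwSd = "numeric",
    smokingPrev = "numeric",
    parityProbs = "numeric",
    unreliableRate = "numeric",
    qpcrNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 0L) msg <- c(msg, "nSubjects must be non-negative")
  if (object@asGeomean <= 0) msg <- c(msg, "asGeomean must be positive")
  if (object@asGSD <= 1) msg <- c(msg, "asGSD must exceed 1 (multiplicative SD)")
  if (object@asLOD <= 0) msg <- c(msg, "asLOD must be positive")
  if (object@maternalCordLogCorr < 0 || object@maternalCordLogCorr > 1)
    msg <- c(msg, "maternalCordLogCorr must lie in [0, 1]")
  if (any(object@gaWeeks < 20L) || any(object@gaWeeks > 45L))
    msg <- c(msg, "gaWeeks must lie within 20-45 completed weeks")
  if (length(object@gaProbs) != length(object@gaWeeks) ||
      any(object@gaProbs < 0) || abs(sum(object@gaProbs) - 1) > 1e-8)
    msg <- c(msg, "gaProbs must be non-negative and sum to 1 over gaWeeks")
  for (s in c("expressionNoiseSd", "residualBwSd", "qpcrNoiseSd"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  if (object@smokingPrev < 0 || object@smokingPrev > 1)
    msg <- c(msg, "smokingPrev must lie in [0, 1]")
  if (length(object@parityProbs) != 3L || any(object@parityProbs < 0) ||
      abs(sum(object@parityProbs) - 1) > 1e-8)
    msg <- c(msg, "parityProbs must be 3 non-negative values summing to 1")
  if (object@unreliableRate < 0 || object@unreliableRate > 1)
    msg <- c(msg, "unreliableRate must lie in [0, 1]")
  if (object@nNullGenes < 0L) msg <- c(msg, "nNullGenes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Arsenic exposure classification
#'
#' Per-subject low/median/high exposure labels together with the log-scale
#' summaries that produced them: thresholds at the geometric mean divided and
#' multiplied by the multiplicative (ln-scale) SD, the geometric mean itself,
#' the ln-scale SD, and the interquartile range of the imputed values.
#'
#' @slot labels factor with levels low, median, high, one per subject.
#' @slot lowThreshold,highThreshold class boundaries (ug/L).
#' @slot geomean geometric mean (ug/L).
#' @slot logSD standard deviation of ln(concentration).
#' @slot iqr interquartile range (ug/L, type-7 quantiles).
#'
#' @seealso [classifyExposure()], [exposureLabels()], [highVsRest()]
#' @export
setClass("ExposureClassing",
  representation(
    labels = "factor",
    lowThreshold = "numeric",
    highThreshold = "numeric",
    geomean = "numeric",
    logSD = "numeric",
    iqr = "numeric"
  )
)

setValidity("ExposureClassing", function(object) {
  msg <- character()
  if (!identical(levels(object@labels), c("low", "median", "high")))
    msg <- c(msg, "labels must have levels low, median, high")
  if (object@lowThreshold > object@geomean ||
      object@geomean > object@highThreshold)
    msg <- c(msg, "thresholds must bracket the geometric mean")
  if (length(msg)) msg else TRUE
})

#' Gestational-age adjusted birth weight
#'
#' Result of regressing birth weight on gestational age (with a quadratic
#' term) separately by sex: per-subject expected weight, the observed/expected
#' ratio and its natural log, and extreme-group labels at mean +/- SD of the
#' ln ratio within sex.
#'
#' @slot table data.frame with columns `sex`, `expected_g`, `ratio`,
#'   `ln_ratio`, `extreme` (factor low/mid/high, NA when birth weight or
#'   gestational age is missing).
#' @slot coefficients list per sex of the fitted (intercept, GA, GA^2)
#'   coefficients.
#' @slot thresholds list per sex of the ln-ratio mean +/- SD boundaries.
#' @slot nMissing number of subjects excluded for missing weight or age.
#'
#' @seealso [fitGAAdjustment()], [bwExtremes()]
#' @export
setClass("GAAdjustment",
  representation(
    table = "data.frame",
    coefficients = "list",
    thresholds = "list",
    nMissing = "integer"
  )
)

#' Interquartile-range scaled regression effect
#'
#' One exposure-outcome effect estimate: the regression coefficient of the
#' continuous exposure rescaled to a change per IQR increase (grams for linear
#' models, an odds ratio for logistic models), its Wald confidence interval
#' and p-value, the covariates retained, model diagnostics, and the estimate
#' refitted without influential subjects.
#'
#' @slot outcome,exposure model variable names.
#' @slot family "gaussian" or "binomial".
#' @slot estimate,ciLow,ciHigh effect per IQR increase (difference in grams,
#'   or odds ratio).
#' @slot p two-sided p-value of the exposure coefficient.
#' @slot n complete cases used.
#' @slot iqr the IQR used for scaling (exposure units).
#' @slot covariates covariates included alongside the exposure.
#' @slot diagnostics list produced by [runDiagnostics()] (empty for logistic
#'   fits or when diagnostics are switched off).
#' @slot refitEstimate estimate after removing influential subjects (NA when
#'   no diagnostics or no influential subjects).
#'
#' @seealso [fitLinearEffect()], [fitLogisticEffect()]
#' @export
setClass("EffectEstimate",
  representation(
    outcome = "character",
    exposure = "character",
    family = "character",
    estimate = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    p = "numeric",
    n = "integer",
    iqr = "numeric",
    covariates = "character",
    diagnostics = "list",
    refitEstimate = "numeric"
  )
)

setValidity("EffectEstimate", function(object) {
  msg <- character()
  if (!(object@ciLow <= object@estimate && object@estimate <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the estimate")
  if (object@family == "binomial" && object@estimate <= 0)
    msg <- c(msg, "odds ratio must be positive")
  if (length(msg)) msg else TRUE
})

#' Dual-contrast quadrant screen result
#'
#' Per-gene statistics of the sex-stratified screen: the mean log2 difference
#' and Welch p-value for the high-versus-low arsenic contrast, the same for
#' the low-versus-high birth weight contrast, the quadrant implied by the two
#' difference signs, and candidate flags. Quadrant 1 holds transcripts up with
#' exposure and up with growth restriction; quadrant 3 the mirror image.
#' No multiple-testing correction is applied to the primary calls;
#' Benjamini-Hochberg q-values are emitted alongside for information only.
#'
#' @slot stratum the sex stratum screened.
#' @slot panel name of the gene panel screened.
#' @slot table data.frame with columns `feature`, `gene`, `d_as`, `p_as`,
#'   `d_bw`, `p_bw`, `quadrant`, `candidate` (concordant quadrant with both
#'   p < 0.05), `labelled` (either p < 0.05, the plot-annotation rule),
#'   `q_as`, `q_bw` (advisory BH).
#' @slot groupSizes named integer vector: samples per contrast group.
#'
#' @seealso [quadrantScreen()], [screenTable()], [candidates()]
#' @export
setClass("QuadrantScreen",
  representation(
    stratum = "character",
    panel = "character",
    table = "data.frame",
    groupSizes = "integer"
  )
)

setValidity("QuadrantScreen", function(object) {
  tab <- object@table
  msg <- character()
  if (nrow(tab)) {
    q1 <- !is.na(tab$quadrant) & tab$quadrant == 1L
    q3 <- !is.na(tab$quadrant) & tab$quadrant == 3L
    if (any(q1 & !(tab$d_as > 0 & tab$d_bw > 0)))
      msg <- c(msg, "quadrant 1 requires both differences positive")
    if (any(q3 & !(tab$d_as < 0 & tab$d_bw < 0)))
      msg <- c(msg, "quadrant 3 requires both differences negative")
    p <- c(tab$p_as, tab$p_bw)
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Baron-Kenny mediation cascade result
#'
#' The four fitted regression models testing a transcript as mediator between
#' dichotomized arsenic exposure (high versus median-or-low) and birth weight:
#' model 1, birth weight on exposure; model 2, mediator expression on
#' exposure; model 3, birth weight on the mediator; model 4, birth weight on
#' mediator and exposure jointly. Mediator effects are reported by sex when
#' the sex-by-mediator cross-product is flagged at p < 0.20. The verdict is
#' "partial" when the exposure effect in model 4 is attenuated but still
#' significant, "full" when it loses significance while all other
#' requirements hold, and "none" otherwise.
#'
#' @slot verdict one of "none", "partial", "full".
#' @slot requirements named logical vector: the four mediation requirements.
#' @slot table data.frame mirroring the four models (model, predictor,
#'   stratum, beta, ci_low, ci_high, p).
#' @slot attenuation beta_As(model 1) - beta_As(model 4), grams.
#' @slot interactionP p-value of the sex-by-mediator cross-product.
#' @slot interactionIncluded whether the cross-product entered models 3-4.
#' @slot alpha significance level used for the requirements.
#' @slot nPerModel complete cases per model.
#' @slot models the four `lm` fits (model1..model4), kept for sensitivity
#'   refits.
#'
#' @seealso [runBaronKenny()], [verdict()], [mediationTable()]
#' @export
setClass("MediationResult",
  representation(
    verdict = "character",
    requirements = "logical",
    table = "data.frame",
    attenuation = "numeric",
    interactionP = "numeric",
    interactionIncluded = "logical",
    alpha = "numeric",
    nPerModel = "integer",
    models = "list"
  )
)

setValidity("MediationResult", function(object) {
  if (!object@verdict %in% c("none", "partial", "full"))
    return("verdict must be one of none, partial, full")
  TRUE
})
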