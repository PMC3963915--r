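#' @importFrom stats rnorm rbinom runif quantile sd qlnorm qnorm pt pf pnorm
#'   complete.cases coef vcov fitted resid lm glm as.formula binomial
#'   p.adjust cor.test ks.test hatvalues rstudent rstandard model.matrix
#'   model.frame setNames drop1 qt terms aggregate
NULL

# Internal: draw covariates and the birth weight equation shared by
# generateCohort and generateReferenceCurves.
simulateSubjects <- function(n, config) {
  mu <- log(config@asGeomean)
  sigma <- log(config@asGSD)
  z1 <- rnorm(n)
  rho <- config@maternalCordLogCorr
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  asCord <- exp(mu + sigma * z1)
  asMaternal <- exp(mu + sigma * z2)
  highClass <- asCord > config@asGeomean * config@asGSD

  sex <- factor(ifelse(rbinom(n, 1, 0.5) == 1, "boys", "girls"),
                levels = c("girls", "boys"))
  smoking <- rbinom(n, 1, config@smokingPrev)
  parity <- factor(sample(c("0", "1", "2+"), n, replace = TRUE,
                          prob = config@parityProbs),
                   levels = c("0", "1", "2+"))
  ga <- sample(config@gaWeeks, n, replace = TRUE, prob = config@gaProbs)

  mediatorExpr <- config@mediatorBaseline +
    config@mediatorLog2FCHighAs * highClass +
    rnorm(n, 0, config@expressionNoiseSd)
  mediatorEffect <- ifelse(sex == "girls",
                           config@mediatorBwEffectGirls,
                           config@mediatorBwEffectBoys)

  iqr <- theoreticalIqr(config)
  linpred <- config@bwIntercept +
    config@betaGA * ga +
    config@betaSexBoys * (sex == "boys") +
    config@betaSmoking * smoking +
    config@betaParity0 * (parity == "0") +
    config@betaParity1 * (parity == "1") +
    config@betaAsPerIqr * asCord / iqr +
    config@betaAsHighGroup * highClass +
    mediatorEffect * (mediatorExpr - config@mediatorBaseline)
  bw <- linpred + rnorm(n, 0, config@residualBwSd)

  list(asCord = asCord, asMaternal = asMaternal, highClass = highClass,
       sex = sex, smoking = smoking, parity = parity, ga = ga,
       mediatorExpr = mediatorExpr, linpred = linpred, bw = bw)
}

#' Generate a synthetic mother-newborn cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: cord blood arsenic lognormal with values below the limit of
#' detection flagged censored, maternal arsenic correlated with cord arsenic
#' on the ln scale, and birth weight built from a linear predictor in
#' gestational age, sex, smoking, parity, the latent continuous exposure
#' scaled by its theoretical IQR, an optional dichotomous high-exposure term,
#' and a sex-specific planted mediator pathway, plus Gaussian residual noise.
#' The per-subject latent mediator expression is drawn here so that the
#' expression matrix from [generateExpression()] and the birth weights share
#' the planted mediation structure.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `cohort` (data.frame, one row per pair) and
#'   `truth` (a `SyntheticTruth` list carrying the planted coefficients, the
#'   mediator identity, latent uncensored arsenic, the per-subject latent
#'   mediator expression and the noise-free linear predictor).
#' @examples
#' sim <- generateCohort(simConfig(nSubjects = 20, seed = 7))
#' head(sim$cohort)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@nSubjects < 1L) stop("nSubjects must be positive")
  if (!is.na(config@seed)) set.seed(config@seed)
  n <- config@nSubjects
  s <- simulateSubjects(n, config)

  cordCensored <- s$asCord < config@asLOD
  maternalCensored <- s$asMaternal < config@asLOD

  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = s$sex,
    ga_weeks = s$ga,
    parity = s$parity,
    smoking = s$smoking,
    maternal_age = round(rnorm(n, 30.2, 4.3), 1),
    maternal_height_cm = round(rnorm(n, 167, 6.3), 1),
    maternal_bmi = round(pmax(rnorm(n, 24.3, 3.9), 16), 1),
    education = factor(sample(c("low", "middle", "high"), n, replace = TRUE,
                              prob = c(0.20, 0.45, 0.35)),
                       levels = c("low", "middle", "high")),
    complications = rbinom(n, 1, 0.044),
    as_cord_ugL = ifelse(cordCensored, NA_real_, s$asCord),
    as_cord_below_lod = cordCensored,
    as_maternal_ugL = ifelse(maternalCensored, NA_real_, s$asMaternal),
    as_maternal_below_lod = maternalCensored,
    birth_weight_g = s$bw,
    head_circumference_cm = round(13.2 + 0.53 * s$ga +
                                    0.45 * (s$sex == "boys") +
                                    rnorm(n, 0, 1.2), 1),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    mediatorGene = "SFLT1",
    mediatorTranscripts = c("SFLT1_synth_var1", "SFLT1_synth_var2"),
    coefficients = list(
      bwIntercept = config@bwIntercept,
      betaGA = config@betaGA,
      betaSexBoys = config@betaSexBoys,
      betaSmoking = config@betaSmoking,
      betaParity0 = config@betaParity0,
      betaParity1 = config@betaParity1,
      betaAsPerIqr = config@betaAsPerIqr,
      betaAsHighGroup = config@betaAsHighGroup,
      mediatorLog2FCHighAs = config@mediatorLog2FCHighAs,
      mediatorBwEffectGirls = config@mediatorBwEffectGirls,
      mediatorBwEffectBoys = config@mediatorBwEffectBoys
    ),
    theoreticalIqr = theoreticalIqr(config),
    latentAsCord = s$asCord,
    latentAsMaternal = s$asMaternal,
    highClass = s$highClass,
    mediatorExpr = s$mediatorExpr,
    linearPredictor = s$linpred
  ), class = "SyntheticTruth")

  list(cohort = cohort, truth = truth)
}

#' Generate a synthetic expression matrix for a cohort
#'
#' Builds a probe-by-sample log2 intensity matrix emulating quantile-ready
#' single-channel microarray output: the planted mediator gene (two
#' correlated transcript variants, the first carrying the cohort's latent
#' mediator expression), a configurable number of null genes independent of
#' exposure and birth weight, five per-feature-and-sample reliability flags
#' with a small fraction of features failing at least one, and a panel
#' annotation assigning every gene to at least one named panel
#' (embryonal_growth, dna_methylation, oxidative_stress, as_related).
#'
#' @param cohort,truth output of [generateCohort()].
#' @param config the same [SimulationConfig-class].
#' @param replicateFraction fraction of null transcripts spotted as duplicate
#'   probes (replicate probes carry identical values; probe-level artifacts
#'   are out of scope).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assays `log2`
#'   and the five logical flag assays `above_noise`, `below_saturation`,
#'   `not_population_outlier`, `spot_uniform`, `background_not_outlier`;
#'   rowData columns `probe_id`, `transcript`, `gene_symbol`, `panels`.
#' @export
generateExpression <- function(cohort, truth, config, replicateFraction = 0.1) {
  stopifnot(is(config, "SimulationConfig"))
  n <- nrow(cohort)
  stopifnot(length(truth$mediatorExpr) == n)
  nNull <- config@nNullGenes

  nullSymbols <- sprintf("GENE%04d", seq_len(nNull))
  if (truth$mediatorGene %in% nullSymbols)
    stop("mediator gene name collides with a null gene name")
  nullTranscripts <- sprintf("TX%04d", seq_len(nNull))

  # transcript-level expression
  exprList <- list()
  mediatorVar2Noise <- if (config@expressionNoiseSd > 0) 0.35 else 0
  exprList[[truth$mediatorTranscripts[1]]] <- truth$mediatorExpr
  exprList[[truth$mediatorTranscripts[2]]] <- config@mediatorBaseline + 1.5 +
    (truth$mediatorExpr - config@mediatorBaseline) +
    rnorm(n, 0, mediatorVar2Noise)
  baselines <- runif(nNull, 5, 12)
  for (i in seq_len(nNull))
    exprList[[nullTranscripts[i]]] <-
      baselines[i] + rnorm(n, 0, config@expressionNoiseSd)

  transcript <- c(truth$mediatorTranscripts, nullTranscripts)
  symbol <- c(rep(truth$mediatorGene, 2), nullSymbols)

  # probe layout: a fraction of null transcripts replicated twice
  nRep <- floor(nNull * replicateFraction)
  repIdx <- if (nRep > 0) sample(seq_len(nNull), nRep) else integer()
  probeTranscript <- c(transcript,
                       nullTranscripts[repIdx])
  probeSymbol <- c(symbol, nullSymbols[repIdx])
  ord <- order(probeTranscript)
  probeTranscript <- probeTranscript[ord]
  probeSymbol <- probeSymbol[ord]
  nProbes <- length(probeTranscript)
  probeId <- sprintf("P%05d", seq_len(nProbes))

  mat <- do.call(rbind, exprList[probeTranscript])
  dimnames(mat) <- list(probeId, cohort$subject_id)

  flagNames <- c("above_noise", "below_saturation", "not_population_outlier",
                 "spot_uniform", "background_not_outlier")
  flags <- lapply(flagNames, function(f)
    matrix(TRUE, nProbes, n, dimnames = dimnames(mat)))
  names(flags) <- flagNames
  bad <- which(rbinom(nProbes, 1, config@unreliableRate) == 1)
  for (i in bad) {
    f <- sample(flagNames, 1)
    flags[[f]][i, sample(n, 1)] <- FALSE
  }

  panelNames <- c("embryonal_growth", "dna_methylation",
                  "oxidative_stress", "as_related")
  nullPanels <- panelNames[(seq_len(nNull) - 1L) %% 4L + 1L]
  second <- runif(nNull) < 0.1
  nullPanels[second] <- paste(nullPanels[second],
                              panelNames[(seq_len(nNull)[second]) %% 4L + 1L],
                              sep = ",")
  panelByTranscript <- c(setNames(rep("embryonal_growth", 2),
                                  truth$mediatorTranscripts),
                         setNames(nullPanels, nullTranscripts))

  rd <- S4Vectors::DataFrame(
    probe_id = probeId,
    transcript = probeTranscript,
    gene_symbol = probeSymbol,
    panels = unname(panelByTranscript[probeTranscript]),
    row.names = probeId
  )
  cd <- S4Vectors::DataFrame(subject_id = cohort$subject_id,
                             sex = cohort$sex,
                             row.names = cohort$subject_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = c(list(log2 = mat), flags), rowData = rd, colData = cd)
}

#' Derive sex-specific P10 reference growth curves
#'
#' Estimates, for each sex and completed gestational week, the 10th
#' percentile of the generator's own marginal birth weight distribution from
#' a large internal simulation. These self-derived curves stand in for
#' external population reference curves, which are not shipped with the
#' package. The P10 is forced monotone non-decreasing in gestational age by a
#' running maximum.
#'
#' @param config a [SimulationConfig-class].
#' @param nSim internal simulation size (default 200000 subjects).
#' @return data.frame with columns `sex`, `week`, `p10_g`.
#' @export
generateReferenceCurves <- function(config, nSim = 2e5) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.na(config@seed)) set.seed(config@seed + 1L)
  s <- simulateSubjects(nSim, config)
  grid <- expand.grid(sex = levels(s$sex), week = sort(unique(config@gaWeeks)),
                      stringsAsFactors = FALSE)
  p10 <- mapply(function(sx, wk) {
    v <- s$bw[s$sex == sx & s$ga == wk]
    if (!length(v)) NA_real_ else unname(quantile(v, 0.10, type = 7))
  }, grid$sex, grid$week)
  out <- data.frame(sex = grid$sex, week = grid$week, p10_g = p10)
  out <- out[order(out$sex, out$week), ]
  for (sx in unique(out$sex)) {
    i <- out$sex == sx
    out$p10_g[i] <- cummax(out$p10_g[i])
  }
  rownames(out) <- NULL
  out
}

#' Generate qPCR Cq values for a cohort subset
#'
#' Emulates a qPCR confirmation experiment on a subset of samples: Cq values
#' for the two mediator transcript variants (tracking minus one times their
#' log2 expression) and three reference genes (GNB2L1, RPLP0, RPL13A) whose
#' expression is independent of arsenic, with a shared per-sample loading
#' shift and technical Cq noise. By default the subset takes the
#' `nSubset/2` highest and lowest cord arsenic samples, mirroring an
#' extreme-group confirmation design.
#'
#' @param cohort,truth output of [generateCohort()].
#' @param config the same [SimulationConfig-class].
#' @param nSubset number of samples assayed (must not exceed the cohort).
#' @param subjects optional explicit character vector of subject ids.
#' @return data.frame with columns `sample_id`, `target_id`, `cq`,
#'   `efficiency` (fold per cycle, 2.0).
#' @export
generateQPCR <- function(cohort, truth, config, nSubset = 30, subjects = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  targets <- c(truth$mediatorTranscripts, "GNB2L1", "RPLP0", "RPL13A")
  empty <- data.frame(sample_id = character(), target_id = character(),
                      cq = numeric(), efficiency = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(subjects)) {
    if (nSubset > nrow(cohort)) stop("subset larger than cohort")
    if (nSubset == 0) return(empty)
    o <- order(truth$latentAsCord)
    nLow <- floor(nSubset / 2)
    idx <- c(o[seq_len(nLow)], rev(o)[seq_len(nSubset - nLow)])
    subjects <- cohort$subject_id[sort(idx)]
  }
  if (!length(subjects)) return(empty)
  i <- match(subjects, cohort$subject_id)
  if (anyNA(i)) stop("unknown subject ids in subset")

  baseCq <- c(24, 26, 18, 16, 20)
  names(baseCq) <- targets
  loading <- rnorm(length(subjects), 0, 0.4)
  med1 <- truth$mediatorExpr[i] - config@mediatorBaseline
  med2 <- med1 # variant 2 tracks variant 1 (shared latent signal)
  signal <- rbind(med1, med2, 0, 0, 0)

  grid <- expand.grid(t = seq_along(targets), s = seq_along(subjects))
  cq <- baseCq[grid$t] - signal[cbind(grid$t, grid$s)] + loading[grid$s] +
    rnorm(nrow(grid), 0, config@qpcrNoiseSd)
  data.frame(sample_id = subjects[grid$s],
             target_id = targets[grid$t],
             cq = as.numeric(cq),
             efficiency = 2.0,
             stringsAsFactors = FALSE)
}

#' Write and read the planted-truth record
#'
#' The `SyntheticTruth` record round-trips through JSON so simulation ground
#' truth can sit next to exported cohort files.
#'
#' @param truth a `SyntheticTruth` list from [generateCohort()].
#' @param path file path.
#' @return `readTruth` returns the `SyntheticTruth` list.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- as.list(x$coefficients)
  structure(x, class = "SyntheticTruth")
}
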