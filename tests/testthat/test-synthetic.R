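test_that("zero-noise birth weight equals the linear predictor exactly", {
  cfg <- zeroNoiseConfig(n = 80, seed = 11)
  sim <- generateCohort(cfg)
  expect_identical(sim$cohort$birth_weight_g, sim$truth$linearPredictor)
  # deterministic predictor: intercept + GA + sex only under this config
  pred <- cfg@bwIntercept + cfg@betaGA * sim$cohort$ga_weeks +
    cfg@betaSexBoys * (sim$cohort$sex == "boys")
  expect_equal(sim$cohort$birth_weight_g, pred, tolerance = 1e-12)
})

test_that("planted coefficients are recovered from the true design at zero residual", {
  cfg <- simConfig(nSubjects = 400, seed = 12, residualBwSd = 0)
  sim <- generateCohort(cfg)
  co <- sim$cohort
  tr <- sim$truth
  medEffect <- ifelse(co$sex == "girls", 1, 0) *
    (tr$mediatorExpr - cfg@mediatorBaseline)
  medEffectBoys <- ifelse(co$sex == "boys", 1, 0) *
    (tr$mediatorExpr - cfg@mediatorBaseline)
  fit <- lm(co$birth_weight_g ~ co$ga_weeks + I(co$sex == "boys") +
              co$smoking + I(co$parity == "0") + I(co$parity == "1") +
              I(tr$latentAsCord / tr$theoreticalIqr) + medEffect + medEffectBoys)
  got <- unname(coef(fit))
  want <- c(cfg@bwIntercept, cfg@betaGA, cfg@betaSexBoys, cfg@betaSmoking,
            cfg@betaParity0, cfg@betaParity1, cfg@betaAsPerIqr,
            cfg@mediatorBwEffectGirls, cfg@mediatorBwEffectBoys)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- simConfig(nSubjects = 50, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$latentAsCord, b$truth$latentAsCord)
})

test_that("exactly the latent values below the LOD are flagged censored", {
  cfg <- simConfig(nSubjects = 2000, seed = 13, asLOD = 0.2)
  sim <- generateCohort(cfg)
  expect_identical(sim$cohort$as_cord_below_lod,
                   sim$truth$latentAsCord < 0.2)
  expect_true(all(is.na(sim$cohort$as_cord_ugL[sim$cohort$as_cord_below_lod])))
  expect_gt(sum(sim$cohort$as_cord_below_lod), 0)
})

test_that("cord and maternal arsenic correlate on the ln scale as configured", {
  set.seed(14)
  cfg <- simConfig()
  rs <- replicate(200, {
    sim <- generateCohort(cfg)
    cor(log(sim$truth$latentAsCord), log(sim$truth$latentAsMaternal))
  })
  expect_lt(abs(mean(rs) - 0.82), 0.05)
})

test_that("the planted mediator shift is exact at zero expression noise", {
  cfg <- simConfig(nSubjects = 200, seed = 15, expressionNoiseSd = 0)
  sim <- generateCohort(cfg)
  se <- generateExpression(sim$cohort, sim$truth, cfg)
  rd <- SummarizedExperiment::rowData(se)
  i <- which(rd$transcript == sim$truth$mediatorTranscripts[1])
  expect_length(i, 1L)
  x <- SummarizedExperiment::assay(se, "log2")[i, ]
  hi <- sim$truth$highClass
  expect_gt(sum(hi), 2)
  expect_equal(mean(x[hi]) - mean(x[!hi]), 0.30, tolerance = 1e-12)
})

test_that("expression annotation has unique mediator, universal panels and the configured unreliability rate", {
  cfg <- simConfig(nSubjects = 30, seed = 16, nNullGenes = 1000,
                   unreliableRate = 0.05)
  sim <- generateCohort(cfg)
  se <- generateExpression(sim$cohort, sim$truth, cfg)
  rd <- SummarizedExperiment::rowData(se)
  expect_identical(sort(unique(rd$transcript[rd$gene_symbol == "SFLT1"])),
                   sort(sim$truth$mediatorTranscripts))
  expect_true(all(nzchar(rd$panels)))
  # features with at least one failing flag: binomial around nProbes * rate
  nFail <- length(reliableFeatures(se))
  nBad <- nrow(se) - attr(reliableFeatures(se), "nOut")
  expected <- nrow(se) * 0.05
  expect_lt(abs(nBad - expected), 3 * sqrt(nrow(se) * 0.05 * 0.95))
})

test_that("null-gene exposure contrasts are correctly sized", {
  cfg <- simConfig(nSubjects = 183, seed = 17, nNullGenes = 2000,
                   mediatorLog2FCHighAs = 0, unreliableRate = 0)
  sim <- generateCohort(cfg)
  se <- generateExpression(sim$cohort, sim$truth, cfg, replicateFraction = 0)
  mat <- SummarizedExperiment::assay(se, "log2")
  hi <- sim$truth$highClass
  lo <- sim$truth$latentAsCord < cfg@asGeomean / cfg@asGSD
  pvals <- apply(mat, 1, function(x) welchT(x[hi], x[lo])$p)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(mat)) + 0.005)
})

test_that("self-derived reference curves are monotone, round-trip, and exact at zero noise", {
  cfg <- zeroNoiseConfig(n = 30, seed = 18)
  curves <- generateReferenceCurves(cfg, nSim = 20000)
  for (s in unique(curves$sex))
    expect_true(!is.unsorted(curves$p10_g[curves$sex == s]))
  pred <- cfg@bwIntercept + cfg@betaGA * curves$week +
    cfg@betaSexBoys * (curves$sex == "boys")
  expect_equal(curves$p10_g, pred, tolerance = 1e-9)

  path <- tempfile(fileext = ".csv")
  writeGrowthCurves(curves, path)
  expect_equal(readGrowthCurves(path), curves, tolerance = 1e-12)
})

test_that("about 10 percent of a fresh cohort is SGA against self-derived curves", {
  cfg <- simConfig(nSubjects = 5000, seed = 19)
  curves <- generateReferenceCurves(cfg, nSim = 1e5)
  sim <- generateCohort(simConfig(nSubjects = 5000, seed = 20))
  sga <- classifySGA(sim$cohort$birth_weight_g, sim$cohort$ga_weeks,
                     sim$cohort$sex, curves)
  expect_lt(abs(mean(sga) - 0.10), 0.015)
})

test_that("qPCR generation respects subset contracts and inverts exactly at zero noise", {
  cfg <- simConfig(nSubjects = 40, seed = 21, qpcrNoiseSd = 0)
  sim <- generateCohort(cfg)
  expect_error(generateQPCR(sim$cohort, sim$truth, cfg, nSubset = 41),
               "larger than cohort")
  empty <- generateQPCR(sim$cohort, sim$truth, cfg, nSubset = 0)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("sample_id", "target_id", "cq", "efficiency"))

  cq <- generateQPCR(sim$cohort, sim$truth, cfg, nSubset = 20)
  rq <- relativeQuantify(cq, c("GNB2L1", "RPLP0", "RPL13A"))
  v1 <- rq[rq$target_id == sim$truth$mediatorTranscripts[1], ]
  ref <- sort(unique(cq$sample_id))[1]
  idx <- match(v1$sample_id, sim$cohort$subject_id)
  planted <- sim$truth$mediatorExpr[idx] -
    sim$truth$mediatorExpr[match(ref, sim$cohort$subject_id)]
  expect_equal(v1$log2_fc, planted, tolerance = 1e-10)
})

test_that("the truth record round-trips through JSON", {
  sim <- generateCohort(simConfig(nSubjects = 12, seed = 22))
  path <- tempfile(fileext = ".json")
  writeTruth(sim$truth, path)
  back <- readTruth(path)
  expect_equal(back$coefficients, sim$truth$coefficients, tolerance = 1e-12)
  expect_equal(back$latentAsCord, sim$truth$latentAsCord, tolerance = 1e-12)
  expect_identical(back$mediatorGene, sim$truth$mediatorGene)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(asGSD = 0.9), "asGSD")
  expect_error(simConfig(maternalCordLogCorr = 1.2), "maternalCordLogCorr")
  expect_error(simConfig(gaWeeks = 10:12, gaProbs = rep(1 / 3, 3)), "gaWeeks")
  expect_error(simConfig(parityProbs = c(0.5, 0.5)), "parityProbs")
})
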