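test_that("covariate selection keeps forced confounders and strong candidates", {
  set.seed(51)
  n <- 400
  d <- data.frame(sex = rbinom(n, 1, 0.5), smoking = rbinom(n, 1, 0.2),
                  x = rnorm(n), strong = rnorm(n), noise1 = rnorm(n),
                  noise2 = rnorm(n))
  d$y <- 2 * d$x + 10 * d$strong + rnorm(n)
  kept <- selectCovariates(d, "y", "x", c("strong", "noise1", "noise2"))
  expect_true(all(c("sex", "smoking", "strong") %in% kept))
  expect_false(any(c("noise1", "noise2") %in% kept))
  expect_identical(selectCovariates(d, "y", "x", character()),
                   c("sex", "smoking"))
})

test_that("pure-noise candidates are retained at about the nominal 5 percent", {
  set.seed(52)
  hits <- replicate(300, {
    n <- 300
    d <- data.frame(x = rnorm(n), cand = rnorm(n), y = rnorm(n))
    "cand" %in% selectCovariates(d, "y", "x", "cand", forced = character())
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})

test_that("the linear effect recovers a planted per-IQR coefficient exactly at zero noise", {
  cfg <- simConfig(nSubjects = 183, seed = 53, residualBwSd = 0,
                   mediatorLog2FCHighAs = 0, mediatorBwEffectGirls = 0,
                   mediatorBwEffectBoys = 0)
  sim <- generateCohort(cfg)
  d <- sim$cohort
  d$as_imp <- imputeBelowLOD(d$as_cord_ugL, cfg@asLOD, d$as_cord_below_lod)
  d$as_imp[d$as_cord_below_lod] <- sim$truth$latentAsCord[d$as_cord_below_lod]
  eff <- suppressWarnings(
    fitLinearEffect(d, "birth_weight_g", "as_imp",
                    c("sex", "ga_weeks", "smoking", "parity"),
                    iqr = sim$truth$theoreticalIqr, diagnostics = FALSE))
  expect_equal(eff@estimate, -47, tolerance = 1e-6)
})

test_that("IQR scaling is an exact multiplicative identity", {
  set.seed(54)
  d <- data.frame(x = rnorm(100), z = rnorm(100))
  d$y <- 3 * d$x + d$z + rnorm(100)
  perUnit <- fitLinearEffect(d, "y", "x", "z", iqr = 1, diagnostics = FALSE)
  perIqr <- fitLinearEffect(d, "y", "x", "z", iqr = 2.34, diagnostics = FALSE)
  expect_identical(perIqr@estimate, perUnit@estimate * 2.34)
  expect_identical(perIqr@ciLow, perUnit@ciLow * 2.34)
  expect_identical(perIqr@p, perUnit@p)
})

test_that("degenerate linear designs error rather than fitting silently", {
  d <- data.frame(x = rep(1, 30), y = rnorm(30), z = rnorm(30))
  expect_error(fitLinearEffect(d, "y", "x", "z", iqr = 1), "constant")
})

test_that("a balanced design with no influential points reproduces the fit on refit", {
  set.seed(55)
  d <- data.frame(x = rep(c(0, 1), 30))
  d$y <- 2 + d$x + rnorm(60, 0, 0.5)
  eff <- fitLinearEffect(d, "y", "x", iqr = 1, diagnostics = TRUE)
  expect_length(eff@diagnostics$influential, 0)
  expect_identical(eff@refitEstimate, eff@estimate)
})

test_that("the logistic fit recovers the closed-form 2x2 odds ratio", {
  d <- data.frame(exposed = rep(c(1, 0), each = 100),
                  case = c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70)))
  eff <- fitLogisticEffect(d, "case", "exposed", iqr = 1)
  expect_equal(eff@estimate, (10 * 70) / (90 * 30), tolerance = 1e-6)
  expect_true(eff@ciLow < eff@estimate && eff@estimate < eff@ciHigh)
})

test_that("perfect separation is an explicit error", {
  d <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                  y = rep(c(0, 1), each = 20))
  expect_error(fitLogisticEffect(d, "y", "x", iqr = 1), "separation")
  d2 <- data.frame(y = c(rep(0, 15), rep(1, 15)), x = rnorm(30))
  expect_error(fitLogisticEffect(d2, "y2", "x", iqr = 1))
})

test_that("interaction testing flags planted effect modification and stratifies", {
  set.seed(56)
  n <- 500
  d <- data.frame(x = rnorm(n),
                  g = factor(sample(c("girls", "boys"), n, replace = TRUE)))
  d$y <- ifelse(d$g == "girls", -3, 3) * d$x + rnorm(n)
  res <- testInteraction(d, "y", "x", "g")
  expect_true(res$flagged)
  expect_lt(res$p, 1e-6)
  slopes <- vapply(res$stratified, function(m) m[1, "Estimate"], numeric(1))
  expect_lt(slopes[["girls"]], 0)
  expect_gt(slopes[["boys"]], 0)
  expect_error(testInteraction(transform(d, g = "girls"), "y", "x", "g"),
               "constant")
})

test_that("the 0.20 cross-product rule flags null interactions at about 20 percent", {
  set.seed(57)
  flags <- replicate(300, {
    n <- 120
    d <- data.frame(x = rnorm(n), g = factor(rep(c("a", "b"), n / 2)))
    d$y <- d$x + rnorm(n)
    testInteraction(d, "y", "x", "g")$flagged
  })
  expect_lt(abs(mean(flags) - 0.20), 3 * sqrt(0.2 * 0.8 / 300) + 0.01)
})

test_that("diagnostics flag gross outliers and planted heteroskedasticity", {
  set.seed(58)
  x <- rnorm(100)
  y <- x + rnorm(100, 0, 0.5)
  y[17] <- y[17] + 30
  fit <- lm(y ~ x)
  dg <- runDiagnostics(fit)
  expect_true(17 %in% dg$influential)

  # variance proportional to exposure squared: White must reject at large n
  x <- runif(2000, 1, 3)
  y <- x + rnorm(2000, 0, 0.5 * x^2)
  dg <- runDiagnostics(lm(y ~ x))
  expect_lt(dg$whiteP, 0.05)
})

test_that("diagnostic p-values are calibrated under a correct model", {
  set.seed(59)
  ps <- t(replicate(200, {
    x <- rnorm(150)
    z <- rnorm(150)
    y <- 1 + x + z + rnorm(150)
    dg <- runDiagnostics(lm(y ~ x + z))
    c(ks = dg$ksP, white = dg$whiteP)
  }))
  # White's LM statistic is asymptotically uniform under the null
  expect_gt(stats::ks.test(ps[, "white"], "punif")$p.value, 1e-3)
  # the KS test against a fixed N(0,1) with an estimated residual scale is
  # conservative, never anti-conservative: no excess rejections
  expect_lte(mean(ps[, "ks"] < 0.05), 0.07)
  expect_gt(min(ps[, "ks"]), 0)
})

test_that("lack-of-fit applies only with replicated exposure values", {
  set.seed(60)
  x <- rep(1:5, each = 6)
  yLinear <- 2 * x + rnorm(30)
  dgL <- runDiagnostics(lm(yLinear ~ x))
  expect_true(dgL$lackOfFitApplicable)
  expect_gt(dgL$lackOfFitP, 1e-4)
  yCurved <- x^3 + rnorm(30, 0, 0.5)
  dgC <- runDiagnostics(lm(yCurved ~ x))
  expect_lt(dgC$lackOfFitP, 1e-6)
  xCont <- runif(30)
  dgN <- runDiagnostics(lm(rnorm(30) ~ xCont))
  expect_false(dgN$lackOfFitApplicable)
  expect_true(is.na(dgN$lackOfFitP))
})
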