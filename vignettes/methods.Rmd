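---
title: "Methods: arsenic exposure, cord blood expression and birth weight"
author: "cordMediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arsenic exposure, cord blood expression and birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordMediate)
```

# The scientific problem

Prenatal arsenic exposure, even at the very low concentrations seen in
European cord blood (geometric mean around 0.5 µg/L), has been associated
with reduced birth weight. `cordMediate` implements, as a tested and
reusable pipeline, the analysis chain needed to probe a molecular
explanation of that association in a mother–newborn cohort:

1. **Exposure handling** — limit-of-detection substitution, log-scale
   summaries, and extreme-group classification of cord blood arsenic.
2. **Birth outcomes** — small-for-gestational-age (SGA) status from
   sex-specific P10 reference curves, and a gestational-age-adjusted birth
   weight ratio with its own extreme groups.
3. **Association models** — IQR-scaled linear and logistic exposure effects
   with a-priori confounders, data-driven covariate retention, interaction
   screening and formal diagnostics.
4. **Transcriptomics** — single-channel microarray preprocessing and a
   sex-stratified dual-contrast "quadrant" screen for candidate mediator
   transcripts.
5. **Mediation** — the classical Baron–Kenny four-model cascade testing a
   transcript (such as sFLT1, an anti-angiogenic VEGF scavenger) as
   mediator between dichotomized exposure and birth weight.
6. **qPCR confirmation** — reference-gene stability (geNorm M),
   multi-reference relative quantification, and platform concordance.

Because no individual-level cohort of this design is publicly deposited,
the package ships a **synthetic cohort generator** with a planted mediator
gene. Every synthetic quantity is ground truth, so each stage of the
pipeline can be tested for recovery of known structure.

# Exposure model and classification

Cord blood arsenic is modelled lognormal: `ln(As) ~ N(ln GM, ln GSD)` with
default geometric mean 0.56 µg/L and multiplicative geometric SD 3.25.
Maternal arsenic shares the marginal and correlates with cord arsenic at
r = 0.82 on the ln scale. Values below the limit of detection
(0.028 µg/L; about 0.6% of draws) are flagged censored and substituted by
LOD/2 (`imputeBelowLOD()`).

`classifyExposure()` labels subjects *low*/*median*/*high* using
thresholds at the geometric mean divided/multiplied by `exp(sd(ln As))`.
The "geometric mean ± SD" rule is read **multiplicatively**: with GM
0.56 µg/L an additive reading would give a negative lower bound, whereas
the multiplicative reading reproduces the familiar 0.17/1.81 µg/L
boundaries. Boundary ties classify as *median* (the rule is strictly
"above"/"below"). The ln-scale SD uses the n−1 denominator; with n ≈ 183
the alternative n denominator moves the thresholds by under 0.01 µg/L.
The IQR uses type-7 (linear interpolation) quantiles throughout, so
IQR-scaled effects are exactly reproducible. Under the default lognormal,
the theoretical IQR is ≈ 0.99 µg/L, which is why the per-IQR birth weight
effect of −47 g has the familiar per-0.99-µg/L interpretation.

# Birth weight adjustment and SGA

SGA is birth weight strictly below the sex-specific P10 for the completed
gestational week; curves are per completed week with **no interpolation**
(a missing entry is an error, not a guess). Reference curves are
self-derived from a large internal simulation of the generator's own
marginal birth weight distribution (200 000 subjects by default, P10 per
sex × week, forced monotone by a running maximum) — external national
curves can be supplied in the same (sex, week, p10_g) format.

For the expression screen's outcome contrast, `fitGAAdjustment()` fits
birth weight on gestational age with a quadratic term, separately by sex,
and computes the ln of observed/expected weight. Extreme groups sit at the
arithmetic mean ± SD of that ln ratio, **within sex** (the sex-specific
group counts are the quantities of interest downstream); pooling sexes
before thresholding would shift group membership slightly for cohorts
with a large sex effect. In the degenerate noise-free case (ln-ratio SD
numerically zero, below 1e−12) no subject is labelled extreme, so
numerical fuzz cannot manufacture extreme groups.

# Association workflow

Effects are reported per IQR increase of the continuous exposure:
coefficient × IQR for linear models, `exp(coefficient × IQR)` as an odds
ratio for logistic models, with Wald intervals scaled identically.
Covariate retention ("keep if significant at 0.05") is operationalized as
one-pass backward elimination from the full candidate model, always
dropping the largest p-value first — deterministic and order-independent —
with sex and maternal smoking forced. Interactions are screened liberally:
a cross-product p below 0.20 triggers inclusion and stratified reporting.

Diagnostics follow the classical toolkit: Kolmogorov–Smirnov on
standardized residuals (conservative, since the residual scale is
estimated — the tests verify it never over-rejects), White's general
heteroskedasticity test (the n·R² LM statistic with levels, squares and
cross-products, delegated to `lmtest::bptest` with an explicitly built
White auxiliary design pruned to full rank), and the pure-error
lack-of-fit F test, which requires replicated predictor rows and
otherwise degrades to a flagged "not applicable". Influential subjects are
flagged at leverage > 2p/n or |studentized residual| > 3 — the cutoffs
are documented package choices — and every linear effect is refitted
without them; removing an empty set reproduces the original fit
bit-for-bit.

# Microarray preprocessing and the quadrant screen

Expression lives in a `SummarizedExperiment` with a log2 intensity assay
and five logical reliability-flag assays per feature × sample (above
noise, below saturation, not a population outlier, spot uniform,
background not an outlier). Preprocessing is: quantile normalization on
the log2 scale (`limma::normalizeQuantiles`, ties receiving the mean of
the tied reference quantiles), replicate probes collapsed by the mean with
flags combined conservatively (reliable only if **all** replicates are),
and a reliability filter keeping features whose five flags pass in every
sample of the contrast at hand.

The screen runs two Welch (unequal-variance, Satterthwaite df) contrasts
per gene within one sex stratum: high-versus-low arsenic and
low-versus-high adjusted birth weight. The orientation is fixed so that
quadrant 1 means "up with exposure, up with growth restriction" and
quadrant 3 its mirror; candidate mediators are concordant-quadrant genes
with both p < 0.05. **No multiple-testing correction** is applied to the
primary calls — the screen is a targeted panel analysis, and that policy
is part of the procedure being implemented — but BH q-values are emitted
alongside for information, as is a `labelled` column using the weaker
either-p < 0.05 rule that governs plot annotation. Zero-variance
contrasts yield p = 1 with a warning rather than NaN, and −log10(p)
columns are floored at the smallest positive double so plotting never
sees infinities.

# The Baron–Kenny cascade

Exposure is dichotomized *high* versus *median-or-low* (the `highVsRest()`
collapse). Four linear models are fitted: (1) birth weight on exposure,
adjusted for sex, gestational age, smoking, parity; (2) mediator log2
expression on exposure, adjusted for sex and gestational age only;
(3) birth weight on the mediator, adjusted as in (1); (4) birth weight on
mediator and exposure jointly. The sex × mediator cross-product is
screened at p < 0.20 in model 3 and, when flagged, enters models 3–4 via
a sex-specific-slopes parameterization so each sex's mediator effect is
reported with its own interval. The mediator stays continuous on the log2
scale: its coefficient is exactly "grams per doubling of expression".

Mediation requires all four coefficients significant at α = 0.05 (for
sex-specific models, in at least one stratum — a sex-limited mediator
still mediates). "Full" mediation is operationalized as the model-4
exposure effect losing significance (a finite-sample stand-in for
"drops to zero"); "partial" requires it attenuated in magnitude yet still
significant. The verdict is a pure function of the four fits and α, and
the per-requirement trace is exposed so a cascade that dies at, say,
requirement 2 is visible rather than silent. Sobel or bootstrap indirect
effect intervals and counterfactual estimands are deliberate non-goals:
the classical stepwise procedure is the method under study.

# qPCR confirmation

Efficiency-corrected relative quantities use `E^(−Cq)` (default E = 2,
overridable per target). geNorm's M statistic is the mean SD across
samples of a gene's pairwise log2 ratios against the other reference
genes; sample-wide loading shifts cancel in the ratios. The iterative
least-stable-gene ranking is provided; the pairwise-variation V = 0.15
cut-off is advisory only. Relative quantification normalizes each target
by the geometric mean of the reference genes and anchors fold changes at
an explicit reference sample (default: lexicographically first), which
scores exactly 0. Platform concordance is the Pearson correlation of
paired array and qPCR log2 fold changes, plus the Welch exposure contrast
on each platform.

# The synthetic generator: what it emulates, and what it does not

`generateCohort()` draws, per subject: correlated lognormal cord/maternal
arsenic; sex (1:1); smoking (prevalence 0.12); parity in {0, 1, 2+} with
probabilities (0.45, 0.40, 0.15); gestational age on completed weeks
34–42 from a discrete table peaked at 40 (median 40); and auxiliary
covariates (maternal age, height, BMI, education, a 4.4% complications
flag) independent of everything else in the model. These covariate
distributions are documented choices of plausible values, not population
claims. Birth weight is a linear predictor — intercept −5040 g (set so
mean weight is ≈ 3400 g), +216 g/week, +161 g for boys, −111 g for
smoking, −184/−30 g for parity 0/1 versus 2+, −47 g per theoretical IQR
of the **latent** continuous exposure, an optional dichotomous
high-exposure term, and a sex-specific mediator term — plus Gaussian
noise. The planted mediator's latent log2 expression (baseline 8, +0.30
in the high-arsenic class, girls-only effect of −182 g per doubling by
default) is drawn at cohort time so the expression matrix and the birth
weights share one mediation structure.

Default noise levels are back-calculated from the precision a cohort of
this design reports: a ±157 g model-1 interval for a 31-versus-152
contrast implies a residual birth weight SD near 400 g, and a ±0.25 log2
interval implies a per-subject expression SD near 0.6; those are the
defaults (`residualBwSd = 400`, `expressionNoiseSd = 0.6`).

The generator does **not** emulate probe-level scanner artifacts, dye
chemistry, spatial or batch effects, pre-eclampsia biology, missing-data
mechanisms, or real covariate correlation structure (covariates are
mutually independent). Passing tests therefore demonstrate that the
pipeline recovers planted structure under clean sampling assumptions —
not that it is robust to everything real cohort data can do.

## Planted-truth scenarios and power

`mediationScenarioConfig()` fixes three canonical test beds:

* **partial** — direct high-group deficit −209 g plus the girls-only
  indirect path (0.30 log2 × −182 g/doubling ⇒ ≈ −27 g averaged over
  sexes), so the marginal model-1 contrast is ≈ −236 g. The verdict is a
  conjunction of about five significance tests, so majority recovery at
  n = 183 needs each individual requirement powered near 90%; the
  scenario's noise (`residualBwSd = 240`, `expressionNoiseSd = 0.45`) was
  chosen by a power analysis to meet that target, and measured joint
  recovery is ≈ 0.70. At the CI-derived default noise the joint power is
  well below one half — an instructive reminder that stepwise mediation
  cascades are underpowered even when every ingredient looks adequately
  powered in isolation.
* **full** — no direct effect; the exposure acts on birth weight only
  through the mediator (both sexes, −182 g/doubling). At large n the
  model-4 exposure coefficient estimates a true zero, so the cascade
  returns "full" about 95% of the time.
* **null** — the mediator is independent of exposure and outcome;
  requirement 2 fails and the verdict is "none" in effectively all
  replicates.

The CI-coverage check of the linear exposure effect runs with the
mediator path switched off: with a girls-only mediator planted, a
linear-in-arsenic outcome model is deliberately misspecified, and
coverage of "the" planted effect would be ill-defined. Effects are scaled
by the generator's theoretical IQR so the planted −47 g is the exact
estimand.

## Problem sizes used by the test suite

Simulation sizes were chosen so the full suite runs in about a minute:
10⁵ draws for classification fractions and Welch test size, 10⁴ null
genes for screen calibration, 500/300/20 replicates for the
partial/null/full mediation scenarios, 500 replicates for CI coverage,
and 200-replicate fixtures elsewhere. Monte-Carlo tolerances are 3
standard errors of the quantity under test unless the construction is
exact, in which case tolerances are 1e−6 to 1e−12.

# Numerical choices and degenerate inputs

* Quantile-normalization ties get the mean of the tied reference
  quantiles (the standard "ties" rule; the choice only matters for
  discrete intensities).
* Welch tests with a zero-variance contrast return p = 1 with a warning.
* Exposure classification requires strictly positive values and n ≥ 3;
  all-equal values give a zero ln-SD and everything *median*.
* Logistic separation (fitted probabilities pinned at 0/1, or |coef| >
  20) is an explicit error, never a silently divergent estimate.
* The SGA rule is strict inequality; a weight exactly on the P10 is not
  SGA.
* JSON round-trips of the truth record keep full double precision
  (`digits = NA`).

# Known limitations

* The qPCR loading-shift invariance holds exactly only when all targets
  share one amplification efficiency (the default E = 2); with per-target
  efficiencies the normalization is the standard one but the invariance
  is approximate.
* The synthetic platform concordance is cleaner (r ≈ 0.95) than a real
  array/qPCR comparison (r ≈ 0.6), because array measurement error beyond
  biological variation is not modelled.
* Backward elimination is one documented reading of "retained when
  significant"; forward or bidirectional selection can retain different
  covariate sets in collinear designs.
* The screen tests collapsed transcript sequences and aggregates to gene
  symbol for reporting; per-probe screening would differ for genes whose
  probes disagree.
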