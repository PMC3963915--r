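# cordMediate

Does low-level prenatal arsenic exposure reduce birth weight, and can a
cord-blood transcript explain how? `cordMediate` is an R package for
epidemiologists and molecular toxicologists that implements the complete
analysis chain for that question in a mother–newborn cohort: exposure
classification, birth-outcome derivation, microarray preprocessing, a
sex-stratified dual-contrast screen for candidate mediator genes, and the
classical Baron–Kenny mediation cascade — together with a synthetic
cohort generator with a planted mediator gene (an sFLT1-like
anti-angiogenic transcript) so every stage can be validated against known
ground truth.

## The statistics at the core

* **Exposure groups on the log scale.** Cord blood arsenic is treated as
  lognormal. With geometric mean *GM* and ln-scale SD *s*, subjects are
  *high* when As > GM·eˢ and *low* when As < GM·e⁻ˢ; values below the
  limit of detection are substituted by LOD/2. Regression effects are
  reported per interquartile-range (IQR) increase: β·IQR grams for linear
  models, exp(β·IQR) as an odds ratio for small-for-gestational-age
  (SGA, weight below the sex-specific P10 for the completed week).
* **Quadrant screen.** Within one sex, each panel gene gets two Welch
  contrasts: Δ₁ = mean log2 difference high-vs-low arsenic, Δ₂ = low-vs-
  high adjusted birth weight (observed/expected from a per-sex quadratic
  fit in gestational age). Genes with Δ₁ > 0, Δ₂ > 0 (quadrant 1) or both
  negative (quadrant 3) and both p < 0.05 are candidate mediators; no
  multiple-testing correction is applied in this targeted panel setting
  (BH q-values are attached for information).
* **Baron–Kenny cascade.** Four linear models — birth weight ~ exposure;
  mediator ~ exposure; birth weight ~ mediator; birth weight ~ mediator +
  exposure — with a sex × mediator cross-product screened at p < 0.20.
  All four effects significant plus an attenuated-but-significant
  exposure effect in model 4 ⇒ *partial* mediation; a non-significant
  model-4 exposure effect ⇒ *full*; anything else ⇒ *none*.
* **qPCR confirmation.** geNorm M stability for reference genes,
  multi-reference relative quantification (E^(−Cq), geometric-mean
  normalization, log2 fold changes anchored at a reference sample), and
  Pearson concordance between array and qPCR fold changes.

## Worked example

Simulate a 183-pair cohort with the default planted structure, classify
exposure, screen the embryonal-growth panel in girls, and run the
mediation cascade on the planted mediator:

```r
library(cordMediate)

cfg <- simConfig(seed = 42)
sim <- generateCohort(cfg)

vals <- imputeBelowLOD(sim$cohort$as_cord_ugL, cfg@asLOD,
                       sim$cohort$as_cord_below_lod)
cls <- classifyExposure(vals)
cls
#> ExposureClassing of 183 subjects
#>   geometric mean 0.541 ug/L, ln-scale SD 1.168
#>   thresholds: low < 0.168, high > 1.74 ug/L
#>   counts: low 28 / median 126 / high 29; IQR 0.913 ug/L

adj <- fitGAAdjustment(sim$cohort)
se  <- quantileNormalize(collapseReplicates(
         generateExpression(sim$cohort, sim$truth, cfg)))
scr <- quadrantScreen(se, exposureLabels(cls), bwExtremes(adj),
                      stratum = "girls")
scr
#> QuadrantScreen: girls stratum, panel 'embryonal_growth', 85 features
#>   groups: As high/low 15/15, BW low/high 15/16
#>   candidates (quadrant 1/3, both p < 0.05): SFLT1
```

The screen singles out the planted gene: it sits in quadrant 1 (up with
exposure, up with growth restriction) with p = 0.025 against the arsenic
contrast and p = 0.013 against the birth weight contrast. The cascade
then quantifies its mediating role:

```r
bk <- runBaronKenny(sim$cohort, sim$truth$mediatorExpr)
bk
#> Baron-Kenny mediation cascade
#>   verdict: partial
#>   requirements met: exposure_outcome, exposure_mediator,
#>     mediator_outcome, mediator_outcome_adjusted
#>   sex x mediator interaction: p = 0.0269 (included)
#>   attenuation of the exposure effect: -55.4 g
#>    model predictor stratum     beta    ci_low  ci_high        p
#> 1 model1   as_high     all -368.330 -545.9862 -190.673 6.51e-05
#> 2 model2   as_high     all    0.262    0.0199    0.504 3.41e-02
#> 3 model3  mediator   girls -273.855 -427.6642 -120.045 5.62e-04
#> 4 model3  mediator    boys  -26.419 -181.8634  129.025 7.38e-01
#> 5 model4  mediator   girls -214.060 -367.2010  -60.919 6.42e-03
#> 6 model4  mediator    boys  -31.891 -182.7655  118.984 6.77e-01
#> 7 model4   as_high     all -312.971 -492.3695 -133.572 7.20e-04
```

Reading the table: high-exposed newborns weigh 368 g less (model 1); high
exposure raises mediator expression by 0.26 log2 units (model 2); each
doubling of expression costs 214 g of birth weight in girls but nothing
in boys (model 4, sex interaction included at p = 0.027); and adding the
mediator attenuates the exposure effect from −368 g to −313 g while both
stay significant — partial mediation, exactly the structure that was
planted.

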