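---
title: "Weight-gain-for-gestational-age charts and outcome risk models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-gain-for-gestational-age charts and outcome risk models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgcharts)
```

## The problem

Gestational weight gain (GWG) is a modifiable risk factor for preterm birth,
low birth weight (LBW) and small-for-gestational-age (SGA) infants, but most
GWG standards were built for high-income populations and only for women with
normal baseline BMI. Cohorts in South Asia and Sub-Saharan Africa, where the
burden of these outcomes is highest and underweight BMI is common, need
*internal* reference charts: weight-gain-for-gestational-age percentiles
estimated from the population under study, against which each pregnancy's
total gain can be standardized.

`gwgcharts` implements that pipeline end to end: eligibility filtering,
reference-chart estimation by a longitudinal mixed model, GWG Z-scores and
quartile groups, IOM adequacy ratios, multiple imputation with Rubin's-rules
pooling, and BMI-stratified modified-Poisson risk-ratio models. A synthetic
multi-cohort generator with retained ground truth makes every stage testable.

## The reference model

Visit-level weight gain (visit weight minus baseline weight, kg) is
transformed as

$$y_{ij} = \ln(\text{gain}_{ij} + 5),$$

the +5 kg shift removing negative gains before the natural log, which was
chosen to minimise the skewness of gain distributions. Separately for each
cohort, and only in the **reference subpopulation** (term livebirths whose
first valid weight was taken by 20 weeks), the package fits

$$y_{ij} = f(t_{ij}) + \gamma_{g(i)} + \delta_{g(i)}\, t_{ij} + b_i +
\varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2),\
\varepsilon_{ij} \sim N(0, \sigma_e^2),$$

where $t_{ij}$ is gestational age in weeks, $f$ is a restricted quadratic
spline with four knots at the 5th/35th/65th/95th percentiles of the cohort's
visit gestational ages, $g(i)$ indexes the baseline BMI group (underweight
<18.5, normal 18.5–24.9, overweight 25–29.9, obese ≥30 kg/m²) with a main
effect and an interaction with the *linear* gestational-age term, and $b_i$
is a participant random intercept. Estimation is by REML, because the
variance components — not just the mean — are deliverables: the chart SD is
$\sqrt{\sigma_b^2 + \sigma_e^2}$.

**Restricted quadratic splines.** The term names a basis, not a formula, so
the package adopts the standard epidemiological construction: a linear
column plus, for knots $k_1 < \dots < k_K$,

$$s_j(x) = \frac{(x-k_j)_+^2 - (x-k_K)_+^2}{k_K - k_1}, \quad j = 1..K{-}1,$$

which is continuous with continuous first derivative and **linear beyond the
final knot**. We restrict the upper tail only; this is the conventional
quadratic-spline reading, and the choice is isolated in `rqs_basis()` so an
implementer can swap forms. Quantile knots use the linear-interpolation
quantile definition (the most common default; alternatives move knots by
under a week at realistic sizes).

**Charts.** `reference_chart()` tabulates, per cohort × BMI group × integer
week 8–42, the fixed-effect mean $\mu(t,g)$, the SD, and back-transformed
percentiles $P_p = \exp(\mu + z_p \cdot sd) - 5$ (kg). The SD column is
constant across weeks because the fitted model is homoscedastic; the chart
interface still carries one SD per week so that a heteroscedastic variant
can drop in without changing consumers. The back-transform assumes
normality of $y$ (a shifted-lognormal gain), the natural reading given that
the transform was chosen to symmetrize the distribution. Chart support is
8–42 weeks; requests outside it are refused rather than extrapolated.

## Z-scores, groups, adequacy

Total gain is the last valid weight at or before delivery minus baseline
weight; its gestational week $t$ is the standardization week. The default
Z-score is computed on the transformed scale,

$$z = \frac{\ln(\text{total gain} + 5) - \mu(t)}{sd},$$

with a kg-scale option (standardizing the raw gain against the implied
shifted-lognormal mean/SD) available for sensitivity analyses; the source
analysis does not state which scale it used, and the transformed scale is
the one on which the model is linear and Gaussian. Chart lookup is by
nearest integer week (charts are published per week); linear interpolation
is available behind a flag.

Groups follow the standard-normal quartiles: G1 $z \le \Phi^{-1}(0.25)$,
G2 $(\Phi^{-1}(0.25), 0]$, G3 $(0, \Phi^{-1}(0.75)]$ (the reference), G4
above. Cut-offs are applied at full precision ($\pm 0.6744898$) and only
displayed as ±0.67.

The IOM adequacy ratio is `observed / recommended × 100`, with recommended
gain = first-trimester gain (2 kg underweight/normal, 0.5 kg
overweight/obese) plus the BMI-specific weekly rate (0.51/0.42/0.28/0.22
kg/wk) times (final GA − 13). External standards (e.g. international
normal-BMI standards) are supported only through a plugin interface
(`external_standard_zscore()`) that takes the standard's mean/SD by week and
its declared GA support; no external standard's published coefficients are
embedded. Trimester windows are [14, 28) and ≥28 weeks — the conventional
obstetric windows, stated here as an assumption because the source does not
define them.

## Missing data

Incomplete covariates and outcomes are imputed `m = 50` times (tests use
fewer) by fully-conditional chained equations: Bayesian normal linear
regression for continuous variables, logistic regression with a normal
posterior approximation for binary ones, cycling for a fixed number of
sweeps. This is a deliberate, stated substitute for the joint MCMC imputer
of the source analysis, whose internals (burn-in, iteration counts, model
forms) are unpublished; the conditioning-variable list and m follow the
source exactly. Downstream estimates are pooled by Rubin's rules
($\bar\theta$, $T = W + (1 + 1/m)B$), with log risk ratios pooled on the log
scale. A small-sample t reference is available
(`df = (m-1)(1 + W/((1+1/m)B))^2`).

## Outcome models

Each binary outcome (preterm <37 wk, LBW <2500 g, SGA <10th / <3rd centile,
plus descriptive secondaries) is modelled within BMI strata by a log-link
Poisson working model on the Z-score group with a sandwich (HC0) variance —
"modified Poisson" — which returns risk ratios directly and, on a saturated
2×2 design, equals the closed-form ratio of proportions exactly. Continuous
adjustment covariates (maternal age, enrolment GA, height, continuous BMI)
enter through restricted quadratic splines with three equally spaced
interior knots; parity and previous preterm birth enter as indicators. The
covariate set is fixed to this list; the source's data-driven covariate
screening step is not re-implemented because its criteria are unstated.

Adjusted risks use **marginal standardization**: the average predicted risk
over the stratum's observed covariate distribution with the group set
counterfactually, with delta-method CIs on the log-risk scale. This is a
stated choice — the source reports adjusted risks without naming its
standardization — and a conditional-at-the-means variant would be a
straightforward alternative.

Dose-response curves use logistic regression of the outcome on the
continuous Z-score (again a 3-knot restricted quadratic spline) plus
covariates. With one record per pregnancy and an independence working
correlation, GEE point estimates coincide with ordinary logistic ML, so the
package fits `glm` and reports sandwich variances; per-pregnancy predicted
probabilities are then smoothed against Z within BMI strata by a penalized
regression spline (`mgcv::gam`) and exported on a fixed grid over [−3, 3].
Associations between baseline characteristics and Z-scores use linear
models with cohort-clustered robust SEs (one falls back to HC1 with a
warning when only one cohort is present), mirroring the two different
clustering choices of the source analysis.

## The synthetic generator

`simulate_gwg_cohort()` emulates the study conditions: five cohorts of
2786/2025/3456/6004/1015 pregnancies (labels are generic), a BMI mix of
23.1/60.0/13.4/3.4%, truncated-normal enrolment GA (mean 13.4, SD 3.4,
support [4, 25)), visit counts with median 4 (IQR 3–5) at uniform 4–6-week
gaps, and weights
$w_{ij} = w_{i0} + \exp(\mu^*(t_{ij}) + b_i + \varepsilon_{ij}) - 5$
with $\mu^*$ quadratic in $(t-8)$ on the transformed scale, calibrated so
the median total gain at 39 weeks is 7 kg for normal BMI in the central
cohort, with small cohort intercept shifts and BMI intercept/slope shifts.
Defaults $\sigma_b = 0.10$, $\sigma_e = 0.08$ are desk-scale plausible
values (the source does not report its variance components). Outcome
generation uses two latent standard scores kept in the truth object:
$b_i/\sigma_b$ for gestational-duration outcomes (this avoids circularity
between preterm delivery and visit truncation), and the true standardized
last-visit gain for birth weight (the exposure the pipeline estimates).
Continuous risk models are parameterized
$p_i = p_0 \exp(\beta Z_i - \beta^2/2)$ so that $p_0$ is the *marginal*
risk; a group-RR mode instead fixes risks per true Z-quartile, which is what
the end-to-end recovery tests use. Missingness injection supports MCAR and
MAR-on-observables (masking probability decreasing in maternal education,
calibrated to the target marginal rate), retaining originals for
imputation-quality checks.

What the generator does *not* emulate: measurement rounding and digit
preference, scale drift, twin pregnancies, time-varying covariates,
provider-initiated vs spontaneous preterm subtypes, and the long late-
pregnancy visit schedules that give real cohorts a median last-weight
around 36 weeks (with 4 visits at 4–6-week gaps from a 13-week enrolment,
the synthetic last weight falls near 28–30 weeks; Z-scores are standardized
at that week, so chart validity is unaffected, but the synthetic median
*total* gain is lower than a real cohort's). Passing tests therefore show
that the estimators recover the generating process they assume, not that
real antenatal data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Visit validity is inclusive at the −4/+19 kg boundaries ("more extreme
  than" reads as strict exceedance); only the visit is invalidated, never
  the participant.
* Eligibility and reference exclusions are attributed hierarchically
  (first matching rule), so category counts are mutually exclusive and sum
  to the total excluded.
* Zero-noise inputs: a perfect fixed-effect fit (residual SD < 1e-8) is
  detected before the mixed model is attempted and returned as a degenerate
  fit with both variance components zero — `lme4` cannot represent exactly
  zero residual variance.
* Coincident percentile knots are an error (never silently merged); the
  modified-Poisson GLM runs at epsilon 1e-12 so saturated designs reproduce
  closed forms to near machine precision; aliased covariate columns
  (constant within a stratum) are dropped before fitting.
* Z-group boundaries are closed on the left groups (`z = 0` is G2, matching
  the published "26–50th" convention).
* Groups with zero events report an undefined risk ratio with a diagnostic
  note rather than a spurious number.

## Problem sizes used by the test-suite and acceptance script

Unit tests run on cohorts of 150–3000 participants. The acceptance checks
use: n = 3000 for self-standardization and variance-component recovery;
20 replicates of n = 600 for mean-curve bias at weeks 20/30/40; 100
replicates of n = 5000 for modified-Poisson interval coverage; n = 100,000
for quartile occupancy; and n = 30,000 for the end-to-end recovery of a
simulated G1-vs-G3 LBW risk ratio of 1.6. These sizes give Monte-Carlo
error comfortably inside each check's tolerance.

## Limitations

Charts built this way are *descriptive* references for the population that
produced them. Using them as prescriptive (normative) targets is not
warranted: the cohorts they describe are observational and carry a high
prevalence of adverse outcomes. The constant-SD chart understates fan-out
if real variability grows with gestation (a per-week residual-SD option is
the natural extension); marginal standardization does not address
confounding beyond the measured covariates; and the chained-equations
imputer is congenial only approximately.
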