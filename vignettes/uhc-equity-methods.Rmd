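---
title: "Models and methods for equity-focused UHC monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for equity-focused UHC monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`uhcequity` implements a complete equity-focused monitoring pipeline for
universal health coverage: indicator construction from household-survey
microdata, design-based estimation, wealth-inequality indices, Bayesian
hierarchical trend models with projection to 2030, and hierarchical
determinant models. This vignette records the models, the assumptions
behind them, the tunable parameters, and the design decisions taken where
several defensible choices existed.

## The synthetic study and what it does (and does not) emulate

All development and testing runs on synthetic data with known ground truth.
The generator emulates the structure of the two survey families the
pipeline targets:

* **MICS-like records** (`simulate_mics`): one row per woman with a recent
  birth, observed in repeated cross-sectional waves (defaults 2000, 2006,
  2011, 2018), in 18 governorates split urban/rural. Sampling is two-stage:
  clusters drawn from a finite stratum frame, then households within
  clusters, with weights equal to exact inverse selection probabilities.
  (No post-stratification or non-response adjustment is simulated, which
  keeps design-based variance oracles analytic.) Indicator outcomes are
  Bernoulli draws from a logit-linear model
  `intercept + slope * (year-2000)/10 + wealth_gradient * ridit +
  residence_gap * rural + predictor terms + cluster effect + governorate
  effect`, with normal random effects (default sds 0.3 and 0.2 on the
  logit scale) mirroring the fitted model family so recovery tests are
  well-posed. Full immunisation is derived as BCG & DTP3 & measles all
  received, which makes its coverage bounded by each component by
  construction.
* **HSES-like records** (`simulate_hses`): household consumption, food
  consumption and out-of-pocket (OOP) health spending in two waves
  (defaults 2007, 2012). The OOP share of consumption is zero with
  probability 0.25 (zero-spenders) and logit-normal otherwise, with a wave
  shift (default +1.0 logit) and a wealth tilt (default +0.4 per unit of
  the latent wealth index, richer households spending proportionally more
  on health), plus cluster and governorate effects. The defaults put
  national catastrophic incidence near 2–3% in the first wave and 10–12%
  in the second, the order of magnitude typical of a middle-income setting
  without pooled financing whose OOP dependence is rising. OOP can never
  exceed consumption because it is generated as a share.
* **Predictor series** (`simulate_predictors`): governorate-level
  internally-displaced-person counts (flat baseline, decaying spike from a
  configurable displacement year, default 2014), governorate population
  density (compound growth), and national health expenditure per capita
  (compound growth), observed 2000–2018.

What the generator does **not** emulate: real wealth-index construction
(an index is supplied directly; the surveys ship one), item non-response,
post-stratified or calibrated weights, informative sampling, within-survey
correlation between service indicators beyond shared cluster/governorate
effects, and any real governorate's demography. Passing tests therefore
demonstrate that the estimators recover the truth under a faithful model
of the *design*; they do not certify behaviour under measurement error or
informative non-response.

One master seed drives everything; it is fanned out deterministically per
stage (`fan_seed`), so any stage can be regenerated in isolation and two
runs with the same configuration are byte-identical.

## Design-based estimation

Coverage cells are estimated by the weighted ratio estimator. Standard
errors use ultimate-cluster linearization: first-stage clusters are treated
as the ultimate sampling units within design strata (governorate ×
residence), which is the standard choice when joint inclusion
probabilities are unknown. Single-PSU strata contribute zero variance
rather than forcing a collapse rule. The design-effective denominator
`n_eff = p(1-p)/SE^2` carries the design into the trend model's binomial
likelihood without modelling clusters there explicitly; degenerate cells
(p exactly 0 or 1) fall back to the unweighted count. Empty cells are
reported as missing, never as zero.

Wealth quintiles cut the weighted population distribution at its fifths
using each unit's mass midpoint, so every quintile holds 20% of the
weighted population up to the single unit straddling a cut; ties break by
stable record order for reproducibility.

## Slope and relative indices of inequality

SII and RII are estimated by weighted least squares of the quintile values
on their ridit scores (cumulative population share below the quintile plus
half its own share). Weights are the population shares, multiplied by
inverse variances when the cell standard errors are supplied; zero
standard errors (degenerate cells) are floored at 1e-4 times the largest
cell variance to keep the normal equations well conditioned. The
identity-link fit is the primary estimator because SII is defined as an
absolute difference in percentage points; a logistic-link variant
(quasibinomial fit, predicted at ranks 0 and 1) is available for bounded
outcomes near the extremes. Intervals are delta-method from the WLS
covariance — a sandwich form when cell SEs are supplied, the classical WLS
estimate otherwise. RII is flagged undefined when the fitted value at rank
0 is not positive; SII is still reported. At the default study size
(18 governorates × 2 residences × 6 clusters × 10 households) the
delta-method interval for a null wealth gradient covers zero at close to
the nominal 95%; with many fewer clusters the cell SEs themselves become
noisy and coverage erodes a few points — a cluster-bootstrap is the
recommended alternative there.

## The hierarchical trend model

For one indicator at one aggregation level with groups `g` and time `t`
in decades centred at 2009 (centring decorrelates intercepts and slopes
and improves mixing):

```
y[g,t] ~ Binomial(n_eff[g,t], p[g,t])
logit(p[g,t]) = alpha_g + beta_g * t + sum_k theta_k * x[k,g,t]
alpha_g ~ N(mu_a, sigma_a^2),  beta_g ~ N(mu_b, sigma_b^2)
```

Priors are vague but proper: `N(0, 100^2)` on fixed effects and
hyper-means, half-normal(0, 5) on the hierarchical sds. Group slopes are
random (not a single common slope) because observed group trajectories
converge and diverge; predictor coefficients `theta` are common to all
groups. Sampling is by JAGS (4 chains × 2000 warm-up + 2000 kept draws by
default), with per-parameter split R-hat and effective sample size;
a fit with split R-hat above 1.05 is flagged non-converged and its
projections are emitted but marked. The logit link guarantees projected
coverage strictly inside (0, 1).

Predictors are standardized over their observed span. At governorate
level the subnational series enter per governorate; at residence/quintile
or national level a subnational series is first averaged to a national
series. A single national series observed at four survey waves is close to
collinear with the shared secular trend — the national
health-expenditure series in particular cannot be separated from `mu_b` —
so the pipeline's default predictor set (mirroring a correlation/DIC
screen) uses the subnational IDP and density series at governorate level
and no predictors at the aggregated levels; any set can be requested
explicitly. A zero-variance predictor is flagged as non-informative and
its coefficient simply reproduces the prior.

Projection pushes each posterior draw through the linear predictor for
every year to the horizon (default 2030). For future years the predictor
values are themselves posterior draws from a Bayesian linear trend on the
log scale (identity scale with truncation at zero for series that touch
zero; last observation carried forward below three points), resampled to
align with the MCMC draws, so projection bands reflect both parameter and
predictor uncertainty. The financial-hardship indicators are deliberately
not projected: two waves give no basis for a trend, and this is recorded
as a limitation rather than papered over.

DIC is computed from the package's own deviance trace as
`DIC = mean deviance + pD` with `pD = mean deviance − deviance at the
posterior means`. For the determinant models the deviance uses the
fixed-effect linear predictor, so DIC comparisons there rank fixed-effect
structures.

## The determinant model

Three-level hierarchical logistic regression:

```
logit P(y=1) = b0 + x'b + u_cluster + v_governorate
u ~ N(0, sigma_c^2),  v ~ N(0, sigma_g^2)
```

with weakly informative priors — `N(0, 10^2)` on coefficients (vague on
the odds-ratio scale yet proof against separation blow-ups), half-normal
(0, 2) on the random-effect sds. The random effects are parameterised
non-centred (`u = sigma_c * z`, `z ~ N(0,1)`): with a rare outcome and
~10 households per cluster the data are weakly informative per group and
the centred parameterisation funnels badly (effective sample sizes below
10 for `sigma_c`); the non-centred form restores mixing. Continuous
covariates are centred for conditioning; odds ratios are unaffected.
JAGS's `glm` module is loaded for its block samplers.

Odds ratios are summarized by the posterior **median** (invariant under
reciprocal transformation, so swapping a reference level exactly inverts
the summary) with 2.5/97.5 percentile intervals; reference levels are
printed with OR 1. Reference swapping is implemented as the exact
draw-wise reparameterisation of the stored posterior rather than a refit.
Variance components are reported as posterior medians of `sigma^2` with
credible intervals. Sampling weights are not used in the likelihood — the
multilevel structure carries the design — but a weighted pseudo-likelihood
(zeros-trick, weights normalized to mean one) is available for comparison.

Covariate applicability is outcome-specific: the mother/child covariate
set for the service outcomes (with the documented per-outcome level
exclusions, e.g. the top antenatal-care category for oral rehydration
therapy), the household-head set plus a survey-year indicator for the
financial outcomes, and no wealth quintile for impoverishment (the
consumption-based ranking is mechanically tied to that outcome). Records
in an excluded level are dropped with a message; an unseen category is an
error naming the value. A covariate level unobserved in either outcome
class triggers a separation flag.

## Numerical choices and degenerate inputs

* Catastrophic comparison is strict (`share > threshold`): an exactly-10%
  share is not catastrophic. The denominator defaults to total household
  consumption; non-food and capacity-to-pay variants are labelled options.
* Impoverishment scales consumption per capita (not adult-equivalent) over
  a 30-day recall period by default; both are configurable. Pre-payment
  poor households are never flagged.
* Quintile ties break by stable record order; a constant wealth index is
  an error (quintiles undefined).
* The simulation rejects configurations whose fixed-effect cell coverages
  leave (0.001, 0.999) — Bernoulli draws there carry no information and
  recovery tests would be vacuous.
* MCMC seeds are set per chain from the master seed, so every fit is
  reproducible draw-for-draw given equal library versions.

## Problem sizes used in the test suite

The shipped tests exercise: the default 18-governorate survey
(8,640 woman-records over four waves, 4,320 households over two) for the
pipeline and calibration checks; 18 groups × 4 waves × 500 observations
per cell × 20 replicates for slope recovery (posterior means average
within a few percent of the generating 0.5 logit/decade, 95% intervals
cover it in ≥18 of 20); 50 replicates for the null-gradient SII
calibration; n = 5,000 with 250 clusters in 18 governorates for
odds-ratio recovery (true OR 2.0 recovered within ±0.3); and 10
replicates of nested trend models for DIC selection. These sizes were
chosen to make Monte-Carlo error small relative to the tolerances while
keeping the whole suite comfortably re-runnable on a laptop.

## Known limitations

* Survey-year observations enter the trend model as design-effective
  binomial counts; an alternative is a normal model on the logit of the
  observed proportion with its design SE. The binomial choice respects the
  unit interval and degrades gracefully for extreme cells.
* The SII/RII intervals are design-consistent only through the cell SEs;
  full design consistency would bootstrap first-stage clusters.
* Determinant models ignore sampling weights by default (see above).
* Financial-hardship indicators are not projected.
* The generator's covariates are socially patterned on the wealth index in
  a stylised way; determinant-model tests therefore validate recovery of
  *generated* effects, not substantive epidemiology.
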