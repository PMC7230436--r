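---
title: "A multi-risk-factor Markov cohort model for program evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-risk-factor Markov cohort model for program evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healmod)
```

## The problem

Most economic evaluations of school-based health-promotion programs credit a
program only with its effect on body weight. Programs that also improve
physical activity and fruit and vegetable consumption have direct effects on
chronic disease that bypass weight entirely, so a weight-only evaluation
systematically understates their value. `healmod` implements a lifetime
Markov cohort model in which the program acts on the *joint* distribution of
four risk factors, and the comparison of a weight-only against a four-factor
evaluation of the same program is a first-class output.

## State space and assumptions

States are (weight status × activity × fruit × vegetable) × disease status:
24 risk-factor combinations × 33 disease statuses (none, or one of 32
chronic diseases with established risk-factor links) plus absorbing death —
793 states. Structural assumptions:

* **No comorbidity**: a person occupies at most one disease state, entered
  irreversibly; competing risks allocate the per-cycle incidence among
  diseases in proportion to their adjusted rates.
* **Multiplicative combination, no interactions**: risk factors and disease
  status act multiplicatively on mortality, and risk factors multiplicatively
  on incidence, through ratios standardised against fixed population
  proportions (so a ratio of 1 on every dimension recovers the baseline
  hazard exactly, and the population-averaged adjusted rate equals the
  published rate under independence).
* **Program effect only at the start**: odds multipliers reshape the age-10
  joint distribution; transition probabilities afterwards are those of the
  general population.
* **Same risk-factor dynamics with and without disease**: the joint
  transition model applies in every disease stratum.

The within-cycle event order is mortality → incidence → risk-factor
transition. The order is a modelling convention, fixed and documented here
because the outcome accounting (occupancy at cycle start × cycle length)
makes results mildly order-dependent; no half-cycle correction is applied by
default, matching the plain cohort-accounting convention.

## Key parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| discount rate | fraction/year | 0.015 | conventional rate for long-horizon prevention |
| horizon | years | 84 | age 10 through 93, effectively lifetime |
| cycle length | years | 1 (2 available) | annual accounting; transition model is two-year |
| start age | years | 10 | school-program target age |
| sex mix | proportion female | 0.5 | two parallel sex-specific cohorts, combined |
| program cost | $/participant/year | 50 for 2 years | benchmark schedule; discounted cost $99.26 |
| flat disease cost | $/case-year | 12,174 | benchmark annual attributable cost; per-disease mode available |

Program effects are odds ratios per factor category with the reference
(normal weight; not meeting a recommendation) fixed at 1 — e.g.
`obesity_or = 0.7` is a 30% reduction in the odds of obesity. The composite
is applied factor-by-factor with renormalisation inside every stratum of the
remaining factors, which multiplies the conditional odds of the targeted
categories by exactly the supplied ratio and leaves the marginals of the
other factors unchanged. Because sequential composition is not provably
order-invariant, the order is fixed (weight, activity, fruit, vegetable) and
configurable; on test distributions the order effect is below general
numerical noise but it is not assumed to vanish.

## The joint transition model

Two-year transitions among the 24 combinations follow a multinomial logit
whose linear predictor decomposes into outcome-component main effects
(dummies for overweight, obese, meeting each behaviour), covariate effects on
those components (sex, age, current status of all four factors), and
association terms — products of outcome dummies across factors. The default
structure carries two- and three-way associations, reflecting the
interdependence among the outcomes that motivates joint rather than
factor-by-factor modelling; the structure is an explicit argument, and the
package deliberately does not perform stepwise structure selection.
Age enters linearly as (age − 40)/10; piecewise age bands can be emulated by
fitting separate models.

Fitting maximises the exact multinomial log-likelihood (records aggregated
by covariate pattern) with BFGS plus Newton refinement using the analytic
Hessian, stopping when the per-record gradient norm falls below 1e-6;
standard errors come from the observed information. An optional L2 ridge
(default 0) handles separation. Two independent oracles guard the
implementation: brute-force enumeration of exp(η)/Σexp(η) on hand-set
coefficients, and the closed-form MLE of the saturated intercept-only
model (fitted probabilities must equal observed frequencies).

Annual cycles require one-year matrices from a two-year model: the principal
eigendecomposition square root is taken and projected to the nearest valid
stochastic matrix (negative entries clipped, rows renormalised). A true
embeddable root need not exist; the projection deviation
‖(M^½)² − M‖∞ is recorded on the matrix and is ~1e-15 on generated sets.
Imaginary components above 1e-6 trigger a warning.

## Incidence back-calculation

Where incidence is unavailable but age-specific prevalence and mortality
are published, `solve_incidence()` finds the constant incidence that carries
prevalence across an age interval in a two-state illness–death balance with
differential mortality (the non-diseased hazard is derived so the
population hazard matches the general-population value at the interval
start). The balance is the closed-form solution of S′ = −(i+m₀)S,
C′ = iS − m₁C. Newton–Raphson (numerical derivative) runs to a residual of
1e-10 within 100 iterations, starting from the crude estimate
Δprevalence/interval floored at 1e-8, with bisection fallback on the
bracket [0, 10] whenever a Newton step leaves it; infeasible targets
(prevalence below what zero incidence yields) raise an error rather than
returning a boundary value. Validation is against an independent
forward-simulated discrete cohort, not against any printed formula.

## What the synthetic generator does and does not emulate

`generate_parameter_set()` emulates the *shape* of national inputs:
Gompertz-like hazards increasing in age (≈5e-5·e^(0.085·age), males ×1.4),
childhood risk-factor marginals (70/20/10% weight; 30–40% meeting
behavioural recommendations) jittered on the simplex, transition
coefficients with strong status persistence and positive behaviour
associations, disease incidences of 1e-5–2e-3/year at age 40 rising with
age, relative risks 1.1–1.8 only where the packaged linkage table has a
link, and monotone risk ordering (obese ≥ overweight ≥ normal; not-meeting
≥ meeting). Values are draws, not calibrations: passing tests demonstrate
internal correctness, conservation laws, directional economics and
estimator consistency — not agreement with any country's surveillance data.
Absolute incremental effects from synthetic sets are therefore not
comparable to published absolute numbers, while structural identities (null
behavioural effects giving comparison ratios of exactly 1; beneficial
effects pushing ICER ratios above and ROI ratios below 1) hold by
construction of the model, not of the data.

`generate_null_parameter_set()` is the analytic limit — unit ratios, zero
incidence, zero decrements — on which the cohort must reproduce life-table
survival and discounted life expectancy to machine precision.

## Numerical and design choices

* The printed form of the rate-to-probability transform is implemented as
  p = 1 − exp(−I·t); the exponential's sign is the standard transform and
  the only one yielding probabilities in [0, 1).
* Hazard/incidence adjustments keep the inner Σ P·SMR divisor even though
  standardisation makes it 1, so raw and pre-standardised ratios are both
  accepted (the operation is idempotent).
* Zero-mass strata pass through odds adjustment unchanged (avoids 0/0).
* ICERs use program costs only, not net of savings; savings enter ROI.
* "Weight-only evaluation" means the same model with behavioural odds
  ratios set to 1 — with null behavioural effects the two scenarios are
  bit-identical runs, which is why their ratio is exactly 1.000 rather than
  1 within tolerance.
* PSA hyperparameters: beta by moment matching from point ± relative 95%
  half-width; log-normal with sdlog = log(CI ratio)/1.96; normal for
  coefficients with fitted SEs. The 24-cell initial distribution uses
  per-cell beta draws renormalised to the simplex. Interval estimates are
  per-draw ratios (each simulation computes its own ratio), the
  standard-practice reading. Draw failures are excluded and counted.
* Discounting runs from model start (program start), year 0 undiscounted.
* All randomness is pure in an integer seed; PSA derives per-draw sub-seeds
  from the master seed.

## Problem sizes in the test suite

The suite exercises the full 84-year, 793-state model for traces and
scenario comparisons; parameter recovery uses panels of 20,000 subjects
(with 2,000/16,000 for the consistency-in-n check over three seeds);
Monte-Carlo consistency uses 40,000–50,000 sampled transitions; PSA checks
use 200 simulations with correspondingly loose interval expectations, with
10,000 the recommended production setting.

## Known limitations

* No comorbidity or remission; one-disease states only.
* Transition estimates from two-year self-reported panel data inherit
  measurement error and age-extrapolation below the panel's youngest age;
  extrapolation beyond age 100 warns.
* The matrix-root annualisation is a projection, not an exact embedding.
* Fixed population proportions are used as standardisation weights at every
  age; age-specific weights can be supplied only by re-building parameters
  per age band.
* The monotonicity of QALYs in beneficial effects is verified empirically
  on generated parameter sets, not proven for arbitrary transition models.
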