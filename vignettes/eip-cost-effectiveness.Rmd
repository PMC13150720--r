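---
title: "Methods: a Markov cost-utility model for early intervention in psychosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-utility model for early intervention in psychosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eipcea` implements a decision-analytic cost-utility evaluation of Early
Intervention in Psychosis (EIP) services against community mental health
teams (CMHT), from a health-system perspective. This vignette is the
package's account of the model, its assumptions, the numerical choices
made where the design was genuinely open, and what the synthetic fixture
does and does not demonstrate.

## The cohort model

A closed cohort of people with a first episode of psychosis (FEP) enters
the model in the `ACUTE` state at age 20 (the rounded mean age of the
observational cohort the evaluation emulates) and moves between six
mutually exclusive health states in 3-month cycles:

* `ACUTE` — the first/acute psychotic episode;
* `REMISSION` — symptomatic remission (PANSS-based criteria);
* `RELAPSE` — symptomatic worsening requiring clinical care, a share of it
  inpatient;
* `RESISTANT` — treatment-resistant schizophrenia (non-response to two
  adequate antipsychotic trials);
* `PNS` — persistent negative symptoms despite positive-symptom control;
* `DEAD` — absorbing.

The allowed transitions are data, not code: a 6 x 6 adjacency mask,
defaulting to `default_adjacency()`. The default allows acute episodes to
resolve into remission, resistance or PNS; remission to relapse or develop
PNS; relapses to re-remit or progress to resistance; resistant patients to
re-enter remission (a clozapine-response arrow, removable via config); and
PNS to relapse. Death is reachable from every state.

Mortality is applied first, competing-risk style: in each cycle the death
probability of an alive state is `1 - exp(-rate x HR x 0.25)`, where
`rate` is the age-specific all-cause annual mortality rate from the life
table and `HR` the state's mortality hazard ratio (the hazard ratio
multiplies the *rate*, not the probability — the standard actuarial
treatment). The surviving mass is then split across the allowed
destinations in proportion to the baseline destination shares.

Treatment effects enter on the risk-ratio scale: the synthesis produces a
pooled remission RR (applied by default to `ACUTE -> REMISSION`) and a
relapse RR (applied to `REMISSION -> RELAPSE` only — whether it should
also modify relapse recurrence is not determinable from the sources, and
the narrower reading was adopted). `apply_treatment_effect()` multiplies
the target destination share by the RR, caps the product at 1 (counting
the event, surfaced in PSA diagnostics), and renormalizes the remaining
destinations proportionally. By default the RRs act over the whole
horizon; `effect_duration_years` limits them to the first *N* years for
sensitivity use, since effect persistence is an assumption, not an
observation.

QALYs accumulate as occupancy x health-state utility value (HSUV,
dimensionless in [0, 1]) x 0.25 years per cycle; costs as occupancy x
per-cycle state cost plus a per-strategy program cost for every alive
person. Both are discounted at 3.0% per year, applied at cycle resolution:
cycle *t* carries the factor `(1 + r)^(-t/4)`, so four cycles compound to
exactly one annual discount step. Cycles are valued at start-of-cycle
occupancy; there is no half-cycle correction by default (none is part of
the reference analysis), but `half_cycle_correction = TRUE` switches to a
trapezoidal within-cycle average for sensitivity use. The base-case
horizon is 10 years (40 cycles); scenarios cover 20 y, 30 y and a
lifetime horizon defined as running until the cohort reaches age 80.

## Evidence synthesis: power-prior random-effects meta-analysis

The comparative evidence is an aggregate set of two-arm studies plus one
small single-arm observational cohort (n = 82). These are pooled in an
arm-level random-effects binomial model with a log link: study *i* has a
baseline log-risk `phi_i` (control risk `exp(phi_i)`) and a log risk
ratio `delta_i ~ Normal(mu, tau^2)`; the pooled effect is
`RR = exp(mu)`. Exchangeability across studies is assumed. The
observational cohort's likelihood contribution is raised to a power
`a0` in [0, 1] (a power prior): `a0 = 0` discards it, `a0 = 1` treats it
as an ordinary study, and `weight_sensitivity_curve()` traces the pooled
estimate across the grid.

Open design points, resolved as follows:

* **Cohort comparator.** A single-arm cohort cannot inform a contrast by
  itself. The default policy forms a pseudo-control arm from a
  configurable external control proportion applied to the cohort's
  denominator, with the pseudo-arm's likelihood also raised to `a0`. This
  is an explicit, swappable assumption.
* **Hyperpriors.** Weakly informative defaults:
  `mu ~ Normal(0, 1.5^2)` on the log-RR, `tau ~ Half-Normal(0.5)`,
  `phi_i ~ Normal(-1, 1.5^2)` truncated below 0. All are
  config-overridable; they are stand-ins for any prior an analysis might
  prescribe.
* **Zero cells.** The Bayesian binomial likelihood tolerates zero cells,
  but the stated continuity policy is retained: a study with any empty
  cell has 0.5 added to every cell of both of its arms (and only that
  study). Corrected counts are fractional, so such studies — like the
  weighted cohort arms — are evaluated through a generic binomial
  log-likelihood (the Poisson-zeros device) rather than the native
  binomial node; this also makes the `a0` weighting exact.
* **Risk constraint.** Treatment risks `exp(phi + delta)` are truncated
  just below 1 inside the sampler.

Sampling is MCMC via JAGS: by default 4 chains, 500 adaptation, 1000
warm-up and 1000 kept iterations each, with per-chain seeds derived from
one sampler seed, so fits are reproducible. Convergence is monitored by
split-R-hat (every chain halved) and effective sample size on `mu`; a
split-R-hat above 1.05 flags the fit as unconverged with a warning —
never silently accepted. Posterior RR draws feed the PSA directly
(resampled under a seed by `posterior_rr_draws()`), remission and relapse
paired by draw index; the two outcomes are fitted separately, so the
pairing carries no posterior correlation by construction.

## Economics

The incremental analysis follows the standard definitions: incremental
cost `dC = C_EIP - C_CMHT`, incremental effect `dE = E_EIP - E_CMHT`
(discounted QALYs), `ICER = dC / dE` reported only in the trade-off
quadrants — under dominance the classification replaces the ratio. The
headline ICER is computed from unrounded increments. Net monetary benefit
is `NB(lambda) = lambda x dE - dC` at willingness-to-pay `lambda`
(CLP per QALY); the acceptability curve is the fraction of PSA iterations
in which EIP has the higher net benefit (exact ties count 0.5), and plane
quadrant shares split boundary points evenly so the four shares always
sum to 1.

Costs are carried in 2018 Chilean pesos (CLP). For reporting in USD, one
purchasing-power-parity factor is used, default 403.87 CLP per USD —
derived as the ratio 5,550,044 / 13,742 of a dual-reported cost-per-QALY
value, and overridable in config. WTP benchmarks are expressed as
multiples of a GDP per capita of USD 15,923 (1 GDPpc = 6,430,822 CLP at
the default factor).

## Probabilistic and deterministic sensitivity analysis

The PSA draws every uncertain parameter from its distribution
(`dist_spec`): Dirichlet rows for competing transition shares, beta for
utilities and single probabilities, gamma for costs, lognormal for hazard
and risk ratios — the standard families for bounded and positive
quantities, parameterized by method of moments where inputs are
mean (SE). Within an iteration both strategies see the same baseline
draw (common random numbers); strategies differ only through the risk
ratios and program costs. Per-iteration RNG streams come from a seed
table derived from one master seed, so results are bit-reproducible
regardless of execution order. The reference analysis uses 5000
iterations.

One-way sensitivity (`one_way_sa()`) re-runs the deterministic model at
low/high bounds of named parameters, reporting ICERs and net-benefit
ranges sorted into a tornado table; bounds outside a parameter's support
are rejected. Scenario analysis covers the alternative horizons and point
overrides.

## Value of information

At a fixed `lambda`, the per-person EVPI is
`E[max_s NB_s] - max_s E[NB_s]` over the PSA iterations (clamped at zero
against floating-point noise). Population EVPI multiplies it by the
discounted stream of incident cases,
`sum_{t=0}^{Y-1} cases / (1+r)^t` — the current year undiscounted, a
convention fixed for reproducibility and configurable. The default
incident population is incidence 18.9 per 100,000 person-years times a
20.1-million population (~3,799 cases/year); the eligible-population
definition is an explicit fixture assumption, exposed in config.

Partial EVPI uses the single-loop regression estimator: per strategy, an
additive spline regression (`mgcv::gam`, thin-plate smooths; parameters
with fewer than 10 distinct values enter linearly) estimates the
conditional expectation of NB given the parameter group, and the EVPI
formula is applied to the fitted values. This estimator is deterministic
given the PSA (no tuning parameters) and testable against closed forms:
for linear NB in a normal parameter the package's estimate matches the
normal loss function analytically. Standard errors come from a
nonparametric bootstrap over iterations of the fitted-value matrix (200
resamples); the regression is not refitted per resample, so the SE
reflects Monte Carlo variation conditional on the fitted surfaces.

## The synthetic fixture: what it emulates, and what it does not

No study-level dataset or parameter table is deposited with the source
evaluation, so the package generates its own inputs with known ground
truth:

* `generate_meta_dataset()` — per-outcome sets of six two-arm studies
  (~2,000 participants in total) under the same random-effects binomial
  structure the synthesis assumes: true log-RR, between-study SD `tau`,
  uniform control risks, binomial counts. Generator truths: remission
  RR 1.3 (`tau` 0.15), relapse RR 0.7 (`tau` 0.20) — the aggregate-level
  effect sizes the evaluation reports when observational data are
  excluded.
* `generate_cohort()` — binomial remission/relapse counts for a
  single-arm cohort of n = 82, with outcome rates (remission 0.55,
  relapse 0.15) implying stronger effects than the aggregate studies, so
  that downweighting visibly moves the pooled estimate.
* `generate_life_table()` — a Gompertz schedule
  `rate(age) = 3.835e-5 x exp(0.09 x age)`, chosen so remaining life
  expectancy at age 20 is about 60 years (population life expectancy
  around 80).
* `make_reference_parameter_set()` — a complete parameterization with
  plausible stand-in values for the Chilean FEP pathway (utilities,
  per-cycle GES-style state costs, mortality hazard ratios around the
  2-3x excess mortality of psychosis). It is explicitly *not* a
  transcription of any published table; every slot accepts drop-in
  replacement. Its calibration gate requires the deterministic base case
  to land in the north-east quadrant with an incremental benefit in
  (0.1, 0.5) QALYs over 10 years, and errors otherwise. The EIP program
  cost (235,000 CLP/cycle vs 110,000 for CMHT) was fixed once so the
  point-estimate ICER (~6.06M CLP/QALY) sits just inside the 1-GDPpc
  threshold.

Passing tests on this fixture demonstrates that the machinery is correct
(mass conservation, oracle agreement, calibrated posteriors, identity
checks), *not* that the fixture reproduces any published quantity. One
visible consequence: a six-study draw is a small sample, and the
reference evidence realizes pooled effects (about RR 1.16 / 0.79 at full
cohort weight) somewhat weaker than the generator truths; the
pipeline-coupled base case then lands at ~0.115 incremental QALYs —
inside the calibration band, but with a higher ICER than the
point-estimate run. That spread between realized and true effects is the
kind of uncertainty the evaluation itself is about, and the fixture makes
it observable rather than hiding it.

Features of real data the generators do not emulate: patient covariates
and longitudinal symptom trajectories (only counts are generated),
study-level risk-of-bias differences beyond the single `a0` device,
non-exchangeable study designs, and real tariff schedules.

## Numerical conventions and degenerate inputs

* Transition-row sums are validated to 1e-9; trace rows conserve mass to
  1e-10; Dirichlet draws sum to 1 to 1e-12.
* The conservation identity (full health, no mortality, no discounting,
  10-year run accrues 10.0 QALYs) holds to 1e-12 relative tolerance —
  a 40-term floating-point sum, so bit-exact equality is not claimed.
* The microsimulation validation band is 3 binomial SEs per state per
  cycle plus a 3-agent discreteness allowance: in near-empty states the
  million-agent count is Poisson-like and a single lingering agent
  exceeds a Gaussian band around occupancies of order 1e-8.
* `rr x p > 1` is capped at 1 and counted; `rr = 0` removes a transition
  and returns its mass proportionally; a fixed spec sampled any number of
  times returns its value; an all-fixed parameter set collapses the PSA
  onto the base case exactly (transition rows can be written as bare
  share vectors for this purpose).
* Ties: net-benefit ties contribute 0.5 to the acceptability
  probability; plane boundary points are split evenly between adjacent
  quadrants.
* EVPI is clamped at 0; a zero-variance EVPPI group returns 0 with a
  warning.

## Problem sizes used by the shipped checks

The test suite validates the synthesis with reduced problem sizes chosen
for tight feedback: the calibration check runs 200 replicates of a
4-study meta-analysis (100-300 per arm) with short chains (coverage of
the 95% interval must lie within 95 +- 5 points); the pipeline test uses
120 PSA iterations. The acceptance script runs the full reference
analysis: 5000 PSA iterations, 4-chain syntheses at three cohort
weights, and the complete VOI stage.

## Known limitations

* The pseudo-control construction for the single-arm cohort is a modelling
  convention; other bridges (matched external controls, hierarchical
  commensurate priors) would change the cohort's pull on the pooled
  effect.
* The remission and relapse effects are synthesized independently; any
  real-world correlation between them is not propagated.
* The relapse state carries hospitalization as a cost weight, not as a
  separate state; within-relapse severity heterogeneity is invisible.
* Cost inflation/deflation across years, budget impact, equity and
  societal perspectives are out of scope.
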