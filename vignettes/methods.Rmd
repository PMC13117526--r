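---
title: "Methods: models, design operating characteristics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, design operating characteristics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piglettrials)
```

This vignette documents the statistical models implemented in
`piglettrials`, the assumptions and parameter values they rest on, and the
numerical choices (samplers, tolerances, simulation sizes) made along the
way. The package targets two-arm randomized neuroprotection experiments in
the newborn piglet model of inflammation-amplified hypoxic-ischemic injury:
a vehicle arm and an intravenous-azithromycin arm, with magnetic resonance
spectroscopy (MRS), amplitude-integrated EEG (aEEG), regional
immunohistochemistry (IHC), blood panels and plasma pharmacokinetics (PK)
as outcomes.

## 1. Bayesian probability of superiority

All treatment-effect summaries are posterior probabilities of superiority,
Pr(sup): the posterior mass on the beneficial side of zero for the
treated-minus-vehicle difference, under noninformative priors.

For a two-arm Gaussian comparison with common variance, flat priors on the
arm means and the Jeffreys prior on the variance give a location-scale
Student-t posterior for the difference: centred at the observed difference
`d`, scale `s_p * sqrt(2/n)`, and `2n - 2` degrees of freedom. Hence

```
Pr(sup) = pt(d / (s_p * sqrt(2/n)), df = 2n - 2)
```

(oriented to the benefit direction). `pr_sup_conjugate()` implements this
closed form; it is the oracle against which the samplers below are tested.
A useful exact property: under the null, the `t` statistic has exactly the
posterior's reference distribution, so Pr(sup) is distributed Uniform(0,1)
by the probability integral transform. The test suite checks this by
Kolmogorov-Smirnov on 10,000 simulated null trials.

### Exact sampling instead of MCMC for linear models

For regression-adjusted analyses (`bayes_lm_draws()`), the posterior under
a flat prior on coefficients and a half-Normal prior on the residual SD
factorizes into a one-dimensional marginal for the SD and a Gaussian
conditional for the coefficients. We draw the SD by inverse-CDF sampling on
a dense log-scale grid and then the coefficients exactly from their
conditional normal. This yields independent and identically distributed
posterior draws: there is no burn-in, no autocorrelation, and convergence
diagnostics are trivially clean. For problems of this size (tens of animals,
a handful of coefficients) it is both faster and more reliable than a
general MCMC sampler, which is why MCMC is reserved for the one model that
needs it (below). Split-R-hat over four pseudo-chains is still computed
(`chain_diagnostics()`) as a guard against implementation errors — for an
exact sampler it should be indistinguishable from 1.

### Blocked Gibbs for the aEEG mixed model

The aEEG recovery model is a random-intercept linear mixed model on
Box-Cox-transformed epoch means: treatment, epoch, their interaction, and
an animal-level intercept. Its posterior is explored by a blocked Gibbs
sampler (`gibbs_lmm()`): the fixed effects are drawn with the random
intercepts analytically marginalized (Woodbury identity per animal), then
the random effects are drawn given the fixed effects, and the two variance
components are updated by an independence Metropolis-Hastings step with an
inverse-gamma proposal. Blocking matters: a naive one-at-a-time Gibbs
scheme mixes slowly because fixed effects and random intercepts are highly
correlated a posteriori; the blocked sampler achieves split-R-hat values
indistinguishable from 1 in the test suite at 4 chains x 2,000 draws.

aEEG scores are bounded (0-4) and left-skewed during recovery, so epoch
means are transformed by Box-Cox with a +0.5 offset (scores of 0 occur).
The transformation parameter λ is profiled on the vehicle arm only and then
held fixed for both arms, so the transformation cannot absorb part of the
treatment effect.

## 2. Trial design operating characteristics

`design_spec()` + `simulate_oc()` estimate the design's frequency
properties by simulation: type I error of the superiority rule
(Pr(sup) ≥ 0.95 at the final analysis), power under the design alternative,
and the probability of stopping for futility (Pr(sup) ≤ 0.50) under the
null.

Two closed forms anchor the simulations:

* Under the null, Pr(sup) is exactly Uniform(0,1), so the futility rule
  stops with probability exactly 0.50 and a threshold `c` gives type I
  error exactly `1 - c`. The simulation estimates must agree within Monte
  Carlo error, and the tests enforce a three-standard-error band.
* Under an alternative `delta` with known-variance posteriors, power has a
  normal closed form; with Student-t posteriors the test suite brackets the
  simulated value against the noncentral-t computation.

Sample size (`sample_size_two_arm()`) iterates the exact noncentral-t power
formula for the two-sample t-test and returns the smallest per-group `n`
attaining the target power; `stats::power.t.test()` is used in the tests as
an independent oracle, not in the implementation. At a 0.5 log10-unit
difference, SD 0.4, 80% power and 5% two-sided alpha the answer is 12 per
group (17 at a 0.4 difference).

Simulation sizes are chosen so that Monte Carlo error is small relative to
the quantities reported: 20,000 trials in the acceptance script (MC
standard error about 0.35 percentage points for probabilities near 50%) and
2,000-50,000 in individual tests depending on the tightness of the
assertion. These sizes are the package's own accuracy choices.

## 3. Pharmacokinetics

### Model

Plasma kinetics follow a two-compartment model with zero-order (infusion)
input, parameterized by clearance `CL`, central volume `V1`,
intercompartmental clearance `Q` and peripheral volume `V2`. Disposition is
biexponential with rates alpha and beta, the roots of
`x^2 - (k10 + k12 + k21) x + k10 k21` where `k10 = CL/V1`, `k12 = Q/V1`,
`k21 = Q/V2`. `pk_concentration()` evaluates the closed-form
within-infusion and post-infusion solutions and superposes doses (kinetics
are linear). An independent check integrates the ODE system piecewise
between infusion boundaries with `deSolve::lsoda` (`pk_profile_ode()`);
the two agree to better than 1e-6 relative error in the tests. Splitting
the integration at dose start/stop times matters: an adaptive stepper that
steps across a rate discontinuity loses several digits.

Derived quantities: terminal half-life `log(2)/beta`; total exposure by
exact mass balance `AUC_inf = dose/CL`; Cmax by analytic evaluation at
infusion ends (profiles peak at the end of an infusion for this model)
verified against a fine grid.

### Default parameters and their limits

The defaults (`pk_params_default()`: CL 3.25 L/h, V1 4 L, Q 2 L/h, V2 60 L)
were chosen to reproduce two well-established summary values for neonatal
intravenous azithromycin at a 40 mg dose (20 mg/kg in a 2 kg piglet):
terminal half-life ≈ 33 h and AUC_inf ≈ 12.3 mg·h/L.

```{r derived}
dp <- derived_params(pk_params_default(), dose_regimen(1, 1, 40))
c(t_half_h = dp$t_half_beta, auc = dp$auc_inf, cmax = dp$cmax)
```

Those two constraints do not pin down all four parameters; in particular
Cmax depends on `V1`, which neither constraint identifies. The defaults
give a first-dose Cmax near 5.6 mg/L, higher than peak concentrations
typically observed at comparable neonatal dosing (on the order of 2 mg/L).
Users with concentration data should fit their own parameters with
`fit_population()` rather than rely on the defaults for peak-concentration
questions.

### Population fitting and identifiability

`fit_population()` maximizes a proportional-error likelihood
(observation = prediction × (1 + e), e ~ Normal(0, cv²)) on the log
parameter scale, either by naive pooling or by a Laplace-approximate
marginal likelihood with lognormal subject random effects on `CL` (and
optionally `V1`). The inner random-effect optimization is a safeguarded
one-dimensional Newton iteration warm-started from the previous outer step.
Outer optimization uses `nlminb` with relative tolerance 1e-8 (configurable)
and box constraints on the log scale; the residual-SD floor (cv ≥ 1e-4)
keeps the likelihood bounded on noise-free data.

An identifiability point surfaced by the test suite is worth stating:
with a terminal half-life near 34 h, clearance is only weakly identified by
designs that stop sampling at 60 h (under two half-lives). In replicated
fits at that design, between-subject heterogeneity was systematically
absorbed into an inflated `V2` and understated `CL` — and the marginal
(Laplace) likelihood placed its optimum at the same biased point, showing
this is a property of the design, not of the estimator. Extending sampling
to 96 h (about three terminal half-lives) makes `CL` recoverable: in the
packaged test, 100 replicated 12-subject studies with 20% proportional
error and 30% between-subject variability on `CL` recover clearance within
±20% in at least 90% of replicates. Model selection by AIC correctly
prefers the two-compartment model over the one-compartment reduction on
two-compartment data.

## 4. Missing data and the regional IHC panel

Regional IHC densities are completed by chained-equation imputation
(`impute_chained()`): each incomplete numeric column is regressed on the
others, with coefficients and residual SD drawn from their Bayesian
posterior before each imputation draw (so between-imputation variability is
proper), cycled 10 times per imputation. Rank-deficient predictor sets are
handled by QR-based column dropping. Per-imputation estimates are combined
by Rubin's rules with the Barnard-Rubin small-sample degrees of freedom
(`rubin_pool()`). On complete data one imputation reproduces the
complete-data analysis exactly — the identity is asserted in the tests.

`fit_ihc_panel()` analyses one marker across the eight standard regions:
per region, a linear model of density on arm adjusting for sex, per
imputation, pooled by Rubin; Pr(sup) from the pooled Student-t posterior;
and Benjamini-Hochberg adjustment across the eight-region family
(`stats::p.adjust`).

The overall (across-region) effect is deliberately *not* the average of the
per-region posteriors. Regional estimates from the same animals are
positively correlated through animal-level variation, and averaging
independently drawn regional posteriors would understate the overall
standard error by up to a factor of sqrt(8). Instead, the overall effect
is estimated at the animal level: each animal's mean of standardized
regional densities (standardized by the observed per-region mean and SD)
is regressed on arm and sex per imputation, then Rubin-pooled. In a
balanced design this targets the same estimand — the mean standardized
effect — with an honest standard error. A null-calibration test on
zero-effect synthetic trials checks that the overall Pr(sup) does not
produce spurious certainty.

## 5. Bedside scores and repeated measures

* Ramification index: `(process-gridline intersections)^2 / intact somata`
  per sampling field; fields with zero somata are excluded rather than
  scored 0, since the index is undefined there.
* SIRI: `neutrophils × monocytes / lymphocytes`, analyzed longitudinally.
* aEEG: `aggregate_eeg()` reduces hourly scores to 6-hour epoch means with
  explicit partial-epoch handling; `classify_background()` maps mean upper
  and lower margin voltages to the 0-4 background category with overridable
  cutoffs.

Physiology, cytokines and SIRI are analyzed with a repeated-measures mixed
model (`fit_repeated()`): `lmerTest::lmer(value ~ arm * timepoint +
(1 | animal_id))` with Satterthwaite degrees of freedom and
`emmeans` contrasts of arms within timepoints. In a balanced design the
least-squares means equal raw arm-by-time means, and with two arms at a
single timepoint the model degenerates to the two-sample t-test — both
identities are asserted in the tests. Analytes measured on a
concentration scale are log10-transformed with half-detection-limit
substitution for non-detects (`log10_analyte()`).

## 6. The synthetic-trial generator

`generate_trial()` simulates a complete two-arm study (animals, MRS, aEEG
series, regional IHC for four markers, PK samples, blood panels) from a
`trial_config()`. Design choices:

* MRS log10 lactate/N-acetyl-aspartate is Gaussian within arm with a
  configurable treatment shift (default -0.5) and SD (default 0.4) — the
  same scale the design calculations use.
* aEEG is generated as a latent recovery drift per animal, clamped to the
  0-4 score range and rounded, so the observable has the floor/ceiling and
  discreteness of real background scores.
* IHC densities share an animal-level random effect across regions, which
  induces the between-region correlation that the panel analysis must (and
  does) respect; region and marker base densities set realistic scales.
* PK samples apply proportional error to closed-form predictions on the
  dosing schedule (1-hour infusions at 1, 24, 48 h; samples at 2, 25,
  49 h by default).
* Missingness is missing-completely-at-random at a configurable rate
  (default 5%).

Limits: missingness is MCAR only (no outcome-dependent dropout); PK
parameters are fixed within arm apart from the lognormal random effects;
aEEG uses a simple drift rather than a neurophysiological model; no
litter or batch effects. The generator is for validating analysis
machinery — calibration, identities, operating characteristics — not for
simulating biology. Given a seed, output is byte-identical across runs,
and `write_trial_csvs()`/`read_trial_csvs()` round-trip exactly.

## 7. Pipeline

`run_pipeline()` chains the stages (MRS, aEEG, IHC per marker, SIRI,
PK fit) on either a CSV directory or a synthetic configuration, tolerates
per-stage failure without aborting the run, and emits a results table plus
a manifest containing the seed, package version and a content hash of the
results for reproducibility checks. `validate_inputs()` reports schema and
range violations before analysis. A thin command-line wrapper is installed
at `inst/scripts/piglettrial.R` with subcommands `simulate`, `analyze`,
`validate`, `design` and `pk-derive`.
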