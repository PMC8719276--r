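---
title: "Methods: a desk-scale cancer burden estimation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale cancer burden estimation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the pipeline estimates

`oncoburden` implements, at desk scale, the multi-stage estimation chain
used in global cancer burden studies: from registry incidence and
vital-registration (VR) death records through mortality-to-incidence ratio
(MIR) smoothing, ensemble mortality modeling, incidence back-calculation,
survival-based prevalence and disability estimation, to the summary
measures — years of life lost (YLL), years lived with disability (YLD),
disability-adjusted life years (DALY), age-standardized rates (ASR),
annualized rates of change, 95% uncertainty intervals (UI), and
Sociodemographic Index (SDI) stratification.

Real analyses of this kind rest on an enormous proprietary corpus of
registry and VR sources. This package replaces that corpus with a
synthetic world whose ground truth is known exactly, so that every stage
of the chain is testable: the generator defines true MIR, incidence and
mortality surfaces, and the pipeline is judged by how well it recovers
them from noisy, partially observed data.

## The synthetic world

The default world has 8 locations, years 2000-2019, 12 age groups
(0-15, 15-25, ..., 75-80, 80+), two sexes, and 5 cancer groups
(tracheal/bronchus/lung, colon/rectum, stomach, breast, liver). Truth is
constructed as:

* **MIR**: inverse-logit of `(cancer intercept + age slope x (midpoint -
  50) + beta x HAQ + year drift)` with `beta < 0` per cancer, so MIR falls
  as the health-care access and quality (HAQ) covariate rises — the
  structural relationship the MIR model is supposed to recover. HAQ rises
  linearly over time from location-specific baselines spread over
  [35, 80].
* **Incidence**: a unimodal gamma-shaped age schedule per cancer (modal
  ages 62-70), scaled by a cancer-specific peak rate per 100 000 and a sex
  multiplier (breast male 0.02). Mortality is defined as incidence x MIR,
  so the identity M = I x MIR holds on every cell by construction.
* **Populations**: location sizes of roughly 0.6-6 million, a declining
  age pyramid, 1% annual growth.
* **SDI components**: income, education and (inverted) under-25 fertility
  are monotone transforms of HAQ with small location offsets, all scaled
  to [0, 1].

Observation follows the classic registry/VR structure. Registries cover a
Bernoulli fraction (default 0.7) of location-years and report incident
case counts; VR reports deaths in every cell scaled by a completeness
factor (default 0.95). Counts are negative-binomial with dispersion
`noise_scale` (default 0.1; `0` gives Poisson) — overdispersed counts are
the stress case for a ratio-based pipeline, and 0.1 makes a single cell's
MIR ratio carry roughly 30-50% relative noise. A fraction (default 0.15)
of liver-cancer deaths is recoded to the unspecified ICD-10 code C22.9,
the garbage code the preparation stage must redistribute. The generator's
seed controls truth; observation parameters never touch it, so truth and
observation are strictly separated. All randomness is drawn under named,
seed-derived streams (`derive_seed(master, stage)`), and no function
leaves a trace in the global RNG state.

What the generator does **not** emulate: real geography or location
hierarchies, verbal-autopsy misclassification, registry quality drift,
ICD revision changes over time, or cause-of-death assignment error beyond
the single C22.9 garbage class. Passing recovery tests here demonstrates
that the estimation chain is implemented correctly under its own
assumptions, not that it would be unbiased on real registry data.

## Data preparation

ICD-coded deaths are mapped to the cause list by longest-prefix match;
codes outside the malignant ranges (ICD-9 140-209, ICD-10 C00-C96) are
counted and dropped as non-cancer, and Kaposi sarcoma (C46) is counted
and excluded. C22.9 deaths are separated before mapping and redistributed.
The redistribution operation accepts arbitrary weights over liver plus
target cancers (conserving totals exactly); because the synthetic garbage
mechanism recodes true liver deaths, the pipeline's default returns them
to liver, while the data-driven default of the operation itself
(proportional to cell-level cause shares) remains available for worlds
with a different garbage composition. VR deaths are divided by the
declared completeness; estimating completeness is out of scope.

MIR observations are deaths/cases on matched cells, clamped to
(10^-4, 1]. Raw cell ratios under negative-binomial noise are both noisy
and biased once clamped (the cap censors the upper tail), so the pipeline
forms **stabilized observations**: cases and deaths are pooled over a
moving window of adjacent age groups (±1) and years (±2) with identical
availability for numerator and denominator, and the ratio is taken on the
pooled counts. Summing before dividing removes most of the ratio noise
and with it the censoring bias; this is the count-level form of smoothing
MIRs across age and time. The pooled case count becomes the effective
sample size.

## The three-stage MIR model

1. **Covariate prior.** Per cancer and sex, weighted least squares of
   `logit(MIR) ~ age-group effects + beta x HAQ + year trend`, with
   binomial information weights `ess x p(1-p)` evaluated at the *fitted*
   ratios of a first unweighted pass (weighting by observed `p(1-p)`
   correlates weight with noise and biases small-MIR fits upward).
   Collinear terms (eg a constant HAQ) are dropped with a warning. The
   pooling windows behind the observations shrink symmetrically at the
   first and last years and age groups, because a one-sided window pulls
   a trending series toward its interior at the edges.
2. **Space-time residual averaging.** Residuals at observed cells are
   spread over the grid as a normalized weighted average with time weight
   `(1 - |dy|/(window+1))^lambda` (default lambda 0.7), location weight 1
   for the same location and zeta (default 0.3) for others, multiplied by
   observation precision. Cells in slices with no observations keep
   residual 0, so the covariate prior stands where there are no data.
3. **GP posterior.** Per cancer-location-age-sex series, a 1-D Gaussian
   process over years with a squared-exponential kernel (default
   amplitude 0.4 logits, length scale 6 years) anchored on the stage-1+2
   mean. The heteroskedastic nugget is the delta-method binomial logit
   variance `1/(ess x p(1-p))`, with `p` the average of the observed
   ratio and the stage-1+2 mean, inflated by a robust overdispersion
   factor estimated from the standardized residuals of each cancer-sex
   group (median chi-square matching; only applied when a group has at
   least 10 observations). The posterior mean and 1000 joint draws per
   series are inverse-logit transformed and clamped to (0, 1].
   Non-positive-definite systems receive jitter up to 10^-6 before
   failing. One consequence of the adaptive inflation is that the
   data-dominance limit (posterior tracking dense, noise-free
   observations) holds when the stage-1+2 mean can represent the
   observed surface; residual structure the prior cannot express is
   treated as dispersion, which is the robust choice under the noisy
   default world.

An optional moving-average pass (weights 1/4, 1/2, 1/4, renormalized at
boundaries) over adjacent age groups in logit space, on by default,
implements additional age smoothing. Numerical conventions: logit
transforms clamp at 10^-4 from both bounds; draw sampling is Cholesky
with a 10^-8 ridge.

The kernel choice (squared exponential, single length scale) is the
simplest stationary option; the location pooling collapses any hierarchy
to a single zeta because the synthetic world has no regions. On the
default world the posterior mean recovers true MIR with mean absolute
error below 0.05 (the acceptance suite recomputes this).

## The mortality ensemble

Submodels are the cross of two response spaces — log death rate and logit
cause-fraction of the all-cause envelope — with every subset of the
predictive covariates (HAQ, SDI, linear year) up to a configured size,
plus intercept-only models. Age-group effects are structural: every
submodel carries them, the way cause-of-death ensembles treat age, so an
"intercept-only" submodel is an age pattern with no covariates. (Without
this, submodels lacking age effects retain substantial softmax weight —
cell-level holdout scores barely distinguish them — and misallocate
deaths into young age groups, which the young-heavy standard population
then amplifies.) Fitting uses quasi-Poisson count regression with a
population offset, and quasi-binomial regression against envelope deaths,
rather than least squares on `log(deaths + 0.5)`: the additive constant
biases near-zero cells (young ages, male breast) upward, while count
GLMs handle zeros natively and their quasi-likelihood dispersions carry
the overdispersion into coefficient uncertainty honestly. A continuity
count of 0.01 per cell (fit only) prevents quasi-complete separation when
an entire age group has no deaths. MIR-converted registry incidence
enters as pseudo-death observations (cases x estimated MIR) at half
weight (variance inflation 2).

Out-of-sample predictive validity uses 5 seeded folds over location-years
(3 in the small worlds used for repeated simulation). Each submodel is
scored by the RMSE of the log age-standardized death rate (uniform age
weights, symmetric 0.5-per-100k continuity constant) over held-out
location-years. Scoring the standardized rate rather than raw cells is
deliberate: cell-level RMSE is floored by count noise, which compresses
the skill ratio between structured and unstructured submodels, while the
aggregated score directly penalizes misallocating deaths across ages —
the failure mode that matters for the age-standardized estimates the
pipeline reports. Weights are `exp(-rmse/tau)` normalized, with
temperature tau equal to the smallest RMSE; a submodel that fails to fit
receives weight zero.

Draws are apportioned across submodels by the largest-remainder rule, so
exactly `n_draws` columns are produced. Each contributing submodel fills
its slots with parametric-uncertainty samples: coefficients drawn from a
multivariate normal around the fit, pushed through the inverse link. In
the log-rate space the draws are recentered by half the predictive log
variance so the draw mean matches the fitted prediction rather than
`exp(se^2/2)` times it; predictions are capped at the envelope rate
because one cause cannot exceed all-cause mortality.

Parametric coefficient uncertainty alone badly understates predictive
error whenever every submodel shares a structural misfit, so the
ensemble's uncertainty is calibrated to its own measured out-of-sample
error: draws are widened multiplicatively about their cell means
(mean-preserving, so point estimates are untouched) until the lower-tail
reach of the log age-standardized rate per location-year matches the
weighted out-of-sample RMSE. The lower tail is the calibration target
because log-linked ensemble mixtures are right-skewed and empirical
misses concentrate below the interval. The resulting intervals are
deliberately conservative — the out-of-sample error includes holdout
observation noise — with upper bounds that can be wide for low-count
cancers.

The all-cause envelope is synthetic: cancer deaths times a multiplier
(default 6) plus a Gompertz-shaped non-cancer background (80 x
exp(0.045 x age midpoint) per 100 000), with 2% lognormal draw noise. The
background term exists because a bare multiple of cancer deaths vanishes
in young age groups, where an all-cause envelope never does; without it
the scaler's positivity precondition fails and fraction-space submodels
degenerate. Scaling to the envelope is exact per cell and draw; the
pipeline carries a synthetic non-cancer remainder cause through the
scaler (so the cancer causes keep their level while the conservation law
is exercised with realistic headroom) and then drops it from reporting.

This is deliberately a compact two-space GLM ensemble, not a full
cause-of-death ensemble system with spatiotemporal component models and
dozens of covariates; the module's structure (enumerate, validate
out-of-sample, weight, draw, scale) mirrors that architecture at a size
that runs in minutes.

## Incidence, survival, prevalence, YLDs

Incidence is mortality divided by MIR, elementwise per draw, with
divisors floored at 10^-3 and flagged. Relative survival at t = 1..10
years interpolates linearly in (1 - MIR) between shipped best-case
(high-resource) and worst-case (untreated) frontier curves; the fixtures
are synthetic exponential-decay curves anchored at plausible 5-year
survival values and are explicitly not any reference system's internal
curves. Ten-year prevalence is cohort bookkeeping: each incident cohort
contributes `S(t) x exp(-background x t)` person-years at elapsed years
1..10, aged across group boundaries by annual steps with proportional
spill-over (a cohort uniform over its age interval). Cohorts diagnosed
before the first modeled year are not reconstructed, so the first decade
of the series carries partial prevalence; reporting years 2010+ of a
2000-2019 world are in steady state.

Prevalence is partitioned into the four survival phases with placeholder
durations — diagnosis/treatment 3 months (applied to incident cases),
metastatic 4 months and terminal 1 month (applied to deaths) — and
remission as the remainder, floored at zero with proportional rebalancing
so phase person-years always sum to total prevalence. Disability weights
(0.288 diagnosis/treatment, 0.049 remission, 0.451 metastatic, 0.540
terminal) multiply phase person-years to give YLDs. For the five cancers
with procedure-related disability (bladder, breast, colorectal, larynx,
prostate), a simplified proportion model stands in for a full Bayesian
meta-regression: the proportion undergoing the procedure (3-year moving
average) times the cumulative surviving post-10-year population under
background mortality, times a procedure disability weight, added at the
mean level. Any other cancer is rejected by name.

## Summary measures

YLLs are deaths times remaining life expectancy from a shipped reference
life table (synthetic approximation of an aspirational frontier,
strictly decreasing from 81.6 years at the 0-15 midpoint). DALYs are the
draw-wise sum of YLLs and YLDs. ASRs use shipped world-standard age
weights aggregated to the 12 groups; every aggregate level (location,
global, SDI quintile) standardizes its own pooled age-specific rates, so
the ASR of an aggregate is not a weighted mean of member ASRs. Percent
changes and annualized rates of change (log formula by default, geometric
variant behind a flag) are computed per draw and then summarized; UIs are
the 2.5th and 97.5th percentiles of the draws by linear interpolation
between order statistics (quantile type 7) with the arithmetic mean as
the point estimate. SDI is the geometric mean of the three scaled
components; quintile labels are fixed by the final-year values at the
20/40/60/80th percentiles, ties falling to the lower quintile, and a
location keeps one label across all years. Rankings are by absolute DALY
counts, excluding configured causes, with alphabetical tie-breaks and a
tie flag.

## Reproducibility and problem sizes

One master seed spawns per-stage child seeds deterministically, so
re-running a stage alone reproduces the full-pipeline result and two runs
of the same configuration are byte-identical. The default full run
(19 200 cause-cells x 1000 draws) completes in about 1.5 minutes and
roughly 1 GB of memory on one CPU. The test suite uses smaller worlds
(4 locations, 10 years, 6 age groups, 2 cancers, 100-120 draws) for
repeated-simulation checks such as interval coverage, where 200
replicates complete in well under 10 minutes; these sizes are the
package's declared simulation-study design.

## Known limitations

* The MIR-to-survival map is a linear frontier interpolation; real access
  -to-care scaling is more elaborate, so absolute YLD levels inherit the
  fixture curves' shape.
* Sequela durations and disability weights are placeholders with the
  right structure, not transcriptions of any reference table; YLD-side
  worked examples therefore check identities and shares, not levels.
* Procedure-related disability is a proportion model at the mean level;
  its uncertainty is not propagated.
* The ensemble's coefficient-sampling uncertainty omits between-world
  (structural) error; interval coverage is validated empirically on the
  synthetic world instead.
* ICD mapping implements prefix ranges and the single C22.9 garbage
  class, not the full historical code-mapping tables.
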