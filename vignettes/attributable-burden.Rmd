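---
title: "Estimating disease burden attributable to child maltreatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating disease burden attributable to child maltreatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmburden)
library(dplyr)
set.seed(1)
```

# The problem

Child maltreatment — physical abuse, sexual abuse, emotional abuse, neglect
and exposure to domestic violence — is a modifiable risk factor for mental
disorders and health-risk behaviours. Quantifying how much national disease
burden is attributable to it is complicated by two facts:

1. **Maltreatment types co-occur.** Treating the five types as independent
   exposures and adding their attributable burdens double-counts people who
   experienced several types; ignoring multi-type exposure underestimates,
   because risk rises steeply with the number of types experienced.
2. **Survey data are thin at the required disaggregation.** Attribution needs
   exposure prevalence by gender and 5-year age group for each of the
   `2^5 = 32` mutually exclusive patterns of the five types — far beyond what
   direct cell proportions from a survey of a few thousand respondents can
   support.

`cmburden` implements a comparative risk assessment that treats maltreatment
as a single polytomous exposure with 32 categories. The theoretical minimum
risk exposure level (TMREL) is zero exposure: the counterfactual population
in which nobody experienced any maltreatment.

# The pipeline

## 1. Joint prevalence of the 32 patterns

Direct weighted proportions (`direct_prevalence()`) are the benchmark but are
noisy at 32 cells × 28 gender–age strata. `fit_joint_prevalence()` therefore
fits a log-linear (Poisson) model to the weighted cell counts:

* a fixed intercept per stratum (so fitted stratum totals equal observed
  totals),
* one main effect per maltreatment type, interacted with gender and with a
  smooth age basis,
* all ten two-way type×type interactions (plus gender interactions), which
  carry the co-occurrence structure.

The age basis is a second-order fractional polynomial with powers drawn from
{−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 denoting log). The default pair is
`(0, 2)` — log age and age squared — which allows a single interior peak in
prevalence by age; `select_fp = TRUE` searches all 36 pairs by deviance
instead. The age covariate is the age-band midpoint (17.5 for the first band,
82.5 for 80+), standardised before fitting for numerical conditioning.
Whether to use exact age or band midpoints is a genuinely open choice; we use
midpoints because all downstream consumers of the table are band-indexed.

Three-way and higher exposure interactions are deliberately excluded: the ten
pairwise terms already capture the dominant dependence, and higher-order
terms are exactly the parameters a survey of this size cannot estimate.

Survey weights are rescaled within each stratum to sum to the observed
stratum size, so the scale of the weights cannot masquerade as sample size.
Zero cells receive no added constant; the unsaturated model structure yields
strictly positive fitted values.

## 2. Relative risks by exposure level

`fit_rr()` estimates relative risks per exposure level with log-binomial
regression (binomial GLM, log link), separately by gender, all ages combined.
Exponentiated level coefficients are RRs against the unexposed reference
(RR = 1 by construction), with Wald 95% intervals on the log scale — the same
scale the downstream lognormal uncertainty sampling assumes.

Two exposure codings are supported:

* **count** — number of types experienced, 0–5 (the base analysis);
* **patterns** — the six most common multi-type patterns (EDV+EA+PA+SA,
  EDV+EA+PA, EDV+EA, all five types, EDV+PA, EDV+SA) as their own levels.
  The remaining 26 patterns are too rare for pattern-specific estimation and
  fall back to their type count (`2_other`, `3_other`, ...). The fallback is
  this package's documented choice; it rests on the observation that risk is
  driven mainly by the *number* of types experienced rather than the specific
  combination.

Adjustment sets: `"simply"` (age, childhood financial stress, geographical
remoteness — the base analysis), `"fully"` (additionally other adverse
childhood experiences and peer/sibling bullying victimisation), `"none"`
(crude). Age enters as standardised log-age and age-squared, mirroring the
prevalence model.

Log-binomial models are prone to non-convergence because the log link does
not respect the unit interval. When the GLM fails, the model is refit as a
Poisson regression with robust (HC0 sandwich) standard errors — the standard
rescue that preserves the RR interpretation — and the output is flagged
(`fallback = TRUE`).

## 3. Population attributable fractions

For stratum proportions $p_i$ over the 32 patterns and pattern relative risks
$RR_i$ (each pattern mapped to its level's RR; $RR = 1$ for the unexposed
pattern),

$$\mathrm{PAF} \;=\; \frac{\sum_i p_i (RR_i - 1)}{1 + \sum_i p_i (RR_i - 1)}
\;=\; \frac{\sum_i p_i RR_i - 1}{\sum_i p_i RR_i}.$$

This is the unique formula consistent with the zero-exposure counterfactual
for a categorical exposure: the test suite verifies `compute_paf()` against
an enumerated-population implementation of the counterfactual definition
$(R_\text{current} - R_\text{TMREL}) / R_\text{current}$ over a thousand
random inputs. The same RRs apply to every age group, so the PAF age profile
is driven entirely by the prevalence age profile: PAFs peak where prevalence
peaks.

## 4. Attributable burden

`attribute_cause()` applies each age–gender PAF to the cause's burden:
attributable deaths/YLL/YLD are PAF × total, and attributable DALYs are the
sum of attributable YLL and YLD. Three mappings need care:

* **Anxiety disorders** are one aggregate cause in burden studies, while the
  survey measures PTSD and GAD. `attribute_anxiety()` splits the aggregate by
  the PTSD share $s$ (from an external mental-health survey; default scalar
  0.25, configurable by stratum): the PTSD PAF applies to $sB$, the GAD PAF —
  a proxy for the other anxiety disorders — to $(1-s)B$, and the parts are
  added. Whether $s$ should vary by age and gender is not settled; the
  default is a scalar because the external split is typically published at
  that granularity.
* **Self-harm**: the PAF for suicide attempts (ever) scales the whole
  intentional self-harm envelope — suicides (deaths, YLL) and non-fatal
  injuries (YLD) — assuming the same relative risk for fatal and non-fatal
  outcomes.
* **Smoking** is a two-step chain: maltreatment raises smoking, and smoking
  causes burden. The smoking PAF is applied to the burden *already
  attributed to tobacco* by the source burden study, never to total burden.
  `attribute_smoking()` refuses tables not flagged
  `burden_type = "attributable"`, which guards against double counting.

Attribution starts at the 15–19 band (estimated from 16–19-year-old
respondents, applied to 15–19 burden to match burden-study age groups);
burden below age 15 receives PAF 0 rather than an error. Comorbidity between
outcomes is not modelled, and mediation is not adjusted for.

## 5. Monte Carlo uncertainty

`run_monte_carlo()` propagates the two dominant sources of sampling
uncertainty — exposure prevalence and relative risks — through the full
PAF→burden chain. Per iteration (default 2,000):

* each stratum's 32 proportions are drawn from a Dirichlet distribution with
  concentration `proportion × effective_n` (the conjugate of the multinomial,
  so draws sum to exactly 1); empty cells get a 0.5 pseudo-count because
  Dirichlet concentrations must be positive;
* relative risks are drawn on the log scale, one draw per
  outcome×gender×level per iteration, shared across all age groups (the same
  RRs apply to every age group, so independent per-age draws would understate
  between-age correlation);
* all PAFs and the attribution chain are recomputed.

95% uncertainty intervals are the 2.5th and 97.5th empirical percentiles
(type-7 linear interpolation between closest ranks, checked against a
sort-based oracle in the tests). Burden envelopes are treated as fixed — no
envelope uncertainty is propagated. Iterations producing non-finite output
are excluded with a warning; more than 1% failures is an error.

**Correlation between level RRs.** Level RRs estimated from one model share
the unexposed reference group and are therefore strongly positively
correlated. When `run_monte_carlo()` receives the package's own `rr_fit`, it
draws the level log-RRs jointly from the fit's multivariate normal (the
stored Wald covariance), which our replicate experiments show is needed for
calibrated intervals: with independent draws, interval coverage of the true
PAF fell well below nominal because the common reference-group shock
dominates the PAF's sampling variance. Externally supplied RR tables carry
only marginal confidence intervals, so they fall back to independent
lognormal draws — `exp(N(log rr, σ))` with
`σ = (log ucl − log lcl)/(2 z_{0.975})` — which reproduces the classic
spreadsheet-based approach and its limitation. `uncertainty_spec(rr_correlation
= "independent")` forces that behaviour for comparison.

# The synthetic-data generator

Real survey microdata of this kind are access-restricted, so the package
ships a generator (`simulate_microdata()`, `simulate_burden_table()`) whose
defaults encode the study conditions the pipeline targets, together with
`ground_truth()`, which returns the exact quantities the pipeline should
recover.

* **Exposures** are drawn from a quadratic exponential (log-linear) joint
  model over the 32 patterns — per-type main effects plus ten pairwise
  interaction terms — sampled by exact enumeration of the normalised 32-cell
  table (32 cells are trivially enumerable; no Gibbs sampling needed). Main
  effects are solved by damped fixed-point iteration so the configured
  marginal prevalences are realised exactly at the reference age. Defaults:
  per-type marginals of (30.1, 37.3, 34.1, 9.7, 42.0)% for women and (34.0,
  18.6, 27.6, 8.1, 37.1)% for men with a shared pairwise log-odds of 0.9
  (women) / 1.0 (men), giving any-maltreatment prevalence of about 67% /
  59% and multi-type prevalence near 39% — the regime reported for the
  population this emulates.
* **Age trend**: each main effect is shifted by
  `a1 (log age − log 42) + a2 (age² − 42²)` with defaults peaking in the
  40–44 band, the band where self-reported prevalence peaks.
* **Confounders**: childhood financial stress and geographical remoteness
  raise both exposure (additive shift on the main effects) and every outcome
  (multiplicative risk). The sensitivity covariates (other adverse childhood
  experiences, bullying victimisation) exist as columns with null effects by
  default so the fully adjusted model can be exercised.
* **Outcomes** are Bernoulli with risk `p0(gender) × RR(number of types) ×`
  confounder multipliers, capped at `1 − 10⁻⁶`; capping signals a
  misconfigured risk model and triggers a warning with the count. Default
  true RR profiles are steepest for PTSD and suicide attempt and shallowest
  for smoking, mimicking the reported dose–response ordering.
* **Burden tables** are generated with DALY = YLL + YLD exactly, non-fatal
  mental-disorder causes, an attributable-type smoking envelope, an
  all-causes envelope, and a 10–14 band that must receive zero attribution.

What the generator does **not** emulate: the real sampling frame and
nonresponse, the national age pyramid (ages are uniform), item-level
measurement error, comorbidity between outcomes, and any mediation structure.
Passing recovery tests therefore demonstrate that the *estimators and
plumbing* are correct under the assumed model class — not that the model
class fits any particular real survey.

# Numerical choices

* Cell-count GLMs use the quasi-Poisson family (weighted counts are
  non-integer); coefficients equal the Poisson fit.
* Log-binomial fits start from the intercept-only solution
  (`log(mean(y))`, slopes 0).
* The exposure-calibration fixed point uses damping 0.3 and tolerance 1e−12.
* Proportions are validated to sum to 1 within 1e−6 on input and 1e−9 on
  model output; `compute_paf()` returns exactly 0 when every RR is 1.
* Percentiles: `stats::quantile(type = 7)`.
* Age labels use the en dash canonically; ASCII hyphens are accepted on
  input and normalised (a real interoperability hazard).
* All generators and the Monte Carlo are pure functions of (configuration,
  seed) and restore the caller's RNG state.

# Problem sizes used by the test suite

The suite validates estimator behaviour at sizes chosen to balance Monte
Carlo error against runtime: exact-distribution convergence at n = 200,000;
RR and PAF recovery at n = 100,000; confidence-interval calibration over 200
replicate surveys of n = 20,000; uncertainty-interval coverage over 200
replicate surveys of n = 5,000 with 500 iterations each; the
enumerated-population PAF oracle over 1,000 random inputs.

# Known limitations

* Published relative-risk tables supply only marginal intervals, so
  spreadsheet-mode uncertainty (supplied tables rather than fitted objects)
  understates PAF variance by ignoring the reference-group correlation
  between levels.
* The prevalence model's effective sample size per stratum is the Kish
  approximation; design-based variance estimation for complex surveys is out
  of scope.
* PAFs assume the same relative risk applies to fatal and non-fatal outcomes
  within a cause, and to every measure (deaths, YLL, YLD) of a cause.
* Negative (protective) exposures are handled only through the natural range
  of the PAF formula.
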