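---
title: "Modelling emotional-state transitions from valence ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling emotional-state transitions from valence ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Trauma-exposed people with probable PTSD (pPTSD) report both emotional
numbing and hyperreactivity. One way to reconcile the two is to describe
the valence response not as a line but as a sigmoid: a numb plateau for
mildly negative material, a steep transition, and a saturated response to
strongly negative material. `valtrans` implements that analysis: VAS
ratings in [0, 1] of images with normative valence on a 1–9 scale are
modelled with a hierarchical five-parameter logistic (5-PL) curve

$$f(x) = d + \frac{a - d}{\left[1 + (x/c)^b\right]^g},$$

where `a` is the lower asymptote (rating of the most negative images),
`d` the upper asymptote (rating of neutral images), `c` locates the
inflection region on the norm-valence scale, `g` is the asymmetry
factor (`g = 1` gives the symmetric 4-PL), and `b` — the Hill slope —
is the scientific quantity of interest: the rate of transition between
the neutral and negative emotional states.

## The hierarchical model

Each participant `i` has a curve parameter tuple drawn from group-level
distributions with the truncation structure used throughout:

* `a_i ~ Beta(alpha1, alpha2)`; `alpha1 ~ Normal(2, 1)` truncated below
  at 1; `alpha2 ~ Normal(10, 1)` untruncated, with a hard positivity
  guard at evaluation (a beta shape must be positive; the prior mass
  below zero is ~8e-24, so the guard never binds in practice).
* `b_i ~ Normal(mu_b, 1)` truncated below at 0.5; `mu_b ~ Normal(2, 1)`
  truncated below at 1.
* `c_i ~ Normal(mu_c, 1)` truncated to [0.5, 5]; `mu_c ~ Normal(2, 1)`
  truncated below at 0.5.
* `d_i ~ Normal(mu_d, 1)` truncated below at 0.5; `mu_d ~ Normal(2, 1)`
  truncated below at 0. The asymmetry between the participant-level and
  group-level lower bounds is kept exactly as stated; the same applies
  to `g_i` (bound 0.8) versus `mu_g` (bound 1).
* `g_i ~ Normal(mu_g, 1)` truncated below at 0.8; `mu_g ~ Normal(4, 1)`
  truncated below at 1.

All constants live in one overridable table, `default_priors()`; the
builders (`build_5pl_model()`, `build_linear_model()`,
`build_en_model()`) accept a `priors` argument for sensitivity work.

**Likelihood.** The observation model is not part of the printed prior
block, so the package makes the minimal choice for continuous VAS data:
`y ~ Normal(f(x), sigma)` with a shared `sigma ~ Half-Normal(0.2)`,
weakly informative on the [0, 1] rating scale. `sigma` is exposed in
the prior table like every other constant. `d` has no upper truncation,
so a priori the curve may exceed 1; the likelihood keeps posteriors
inside the plausible range.

**Linear comparison model.** `f(x) = b x + a` with `mu_a ~ Normal(0,
0.2)` and `mu_b ~ Normal(0, 0.5)`, both truncated below at 0 (negative
values are impossible because ratings are nonnegative). The hierarchy
depth of the comparison model is not dictated by the design, so the
package gives it the same random-participant structure as the 5-PL
(participant-level `a_i`, `b_i` around the group means with SD fixed
at 1, truncated at 0) to keep the LOO comparison like-for-like.

**Emotional numbing extension.** The numbing subscale (PCL-5 items
12–14, range 0–12) is z-transformed (population-SD convention by
default; the choice only rescales the coefficient) and enters the slope
as a fixed-slope random-intercept regression:
`B_i = numbing_z_i * EN + b_i`, `EN ~ Normal(0, 1)`. `extra = "age"`
adds `age_z_i * AGE`, and `extra = "age_interaction"` additionally adds
`numbing_z_i * age_z_i * INT`, each coefficient with a `Normal(0, 1)`
prior. The extension models are fitted to the pooled sample by default
(group-specific fits remain possible by subsetting), matching how the
association is reported for the entire sample.

**Participant-level SDs.** The printed notation fixes the
participant-level SDs at 1. That is implemented literally and is the
default. Because a unit SD is far wider than the realistic
between-participant spread of curve parameters, the group-level means
then carry a posterior SD of about `1/sqrt(n)` regardless of how well
individual curves are measured, and group means whose participant
values sit within about one unit of a truncation bound (always true of
`mu_d`, since `d` is a rating bounded by 1 but its bound is 0.5) pile
up against the group prior's own bound. The option
`estimate_participant_sd = TRUE` replaces the fixed SDs with
half-normal(1) estimated SDs; that variant is sampled with an exact
non-centered parameterization (participant deviates are standard-normal
on the real line and mapped through the truncated-normal inverse CDF),
which removes the funnel geometry that makes the centered version
unsamplable.

## Sampling

`fit_model()` runs the package's adaptive No-U-Turn sampler: bounded
parameters are mapped to unconstrained scales (log and scaled-logit
transforms) with exact Jacobian and truncation-normalization terms;
momenta use a diagonal mass matrix estimated in expanding warmup
windows; the step size is tuned by dual averaging toward
`target_accept` (default 0.8). Defaults mirror the reference sampler
settings: 4 chains, 1000 tuning iterations, 1000 retained draws, no
thinning. Trajectories that drift more than 1000 log-density units are
counted as divergent and reported per draw in `sample_stats`; a
post-warmup divergence rate above 1% raises a structured warning.
Chains start, by default, at a pooled least-squares curve fit with
per-chain jitter (`init = "ls"`); the 5-PL posterior is ridge-shaped
(see below) and chains started at the prior centres can take a long
time to reach the data-supported region. The likelihood and its
gradient are evaluated in compiled code. An alternative engine
(`engine = "jags"`) runs the identical model through JAGS adaptive
MCMC; it is retained as an independent cross-check of the NUTS
implementation (the test suite compares the two posteriors on small
models) but mixes poorly on the 5-PL ridge, where single-site updates
cannot follow the correlated geometry.

Convergence is reported as split-chain rank-normalized R-hat (maximum
of the bulk and folded variants) and rank-normalized bulk/tail
effective sample sizes, computed in-package and cross-checked against
i.i.d. oracles in the tests. The usual bar — R-hat below 1.01 and bulk
ESS above 1000 — is checked after every fit and raises a structured
warning when missed.

## Group comparison and HPD intervals

Groups are compared by fitting the model separately per group and
subtracting the pPTSD draws from the TEC draws parameter by parameter
(`compare_groups()`, pairing by flattened chain-draw index; the two
posteriors are independent, so the pairing is equivalent to random
pairing, which a test verifies). A difference is *robust* when 0 lies
outside the 89% highest-posterior-density interval. `hpd()` returns the
shortest contiguous interval containing `ceiling(0.89 n)` sorted draws,
breaking width ties at the lowest start, and flags (as an attribute)
intervals whose point density falls below the sample average — a hint
of multimodality where a single interval misleads. The group-level mean
of `a`, `alpha1/(alpha1+alpha2)`, is exposed as a derived parameter
`mu_a` so that all five curve parameters can be contrasted.

## Model comparison

`compute_loo()` implements Pareto-smoothed importance-sampling
leave-one-out cross-validation from the pointwise log-likelihood array:
per observation, the importance ratios `1/p(y_i | theta_s)` have their
largest `min(0.2 S, 3 sqrt(S))` values replaced by expected order
statistics of a generalized-Pareto fit (Zhang–Stephens estimator with
the usual prior adjustment of the shape toward 0.5), truncated at the
raw maximum. Observations with Pareto k above 0.7 trigger a warning,
not refitting. The result carries `elpd_loo` (higher is better),
`p_loo`, a standard error from the pointwise variance, and the
per-observation shape diagnostics. `compare_models()` ranks models
(rank 0 best), reports `d_loo` gaps, and assigns weights by stacking of
the pointwise predictive densities (softmax-parameterized convex
optimization); pseudo-BMA+ with a Bayesian bootstrap is available via
`method = "pseudobma"`, and is also the tie-handling convention: for
statistically tied models stacking is flat and pseudo-BMA+ splits the
weight evenly. The PSIS approximation is tested against exact
closed-form leave-one-out on a conjugate normal example.

## The synthetic-data generator

The study's raw ratings are not deposited, so every downstream stage is
exercised on synthetic data with the same structure
(`generate_norms()`, `generate_participants()`):

* **Stimulus norms.** 35 analysed images with normative valence
  increasing strictly from 1.33 (most negative) to 5.0 (neutral) — an
  even grid with monotonicity-preserving jitter — plus 5 positive
  fillers at 5.63–7.09 that are rated with the same curve and filtered
  before modelling. Normative SDs are uniform on [0.8, 1.6], the range
  typical of affective picture norms.
* **Questionnaires.** PCL-5 item vectors are constructed so that the
  intended group label is reproduced by the screening rule for every
  participant: pPTSD vectors have totals drawn around 46.5 (SD 9.7),
  floored at 34, with the four symptom clusters explicitly endorsed;
  TEC vectors have totals around 17.8 (SD 10.1), capped at 33. Numbing
  subscales centre on 7.94 (pPTSD) and 2.95 (TEC); ages on 36.1 and
  41.5 years. These are the sample statistics of the study population.
* **Curves.** Participant parameters are drawn from the truncated
  group-level laws with configurable true means and SDs. Defaults:
  `a ~ Beta(2, 10)` (mean 1/6, the centre of the analysis prior —
  most negative images rated near the floor), true inflection
  `mu_c = 3.0`, `mu_d = 0.55` (neutral images near the scale
  midpoint), `mu_g = 1.5` (mild asymmetry), and group slope means 2.2
  (TEC) vs 2.45 (pPTSD) — the same 0.25 gap as the reported group
  effect, at a level interior to the group prior's truncation so the
  group mean is estimable. The defaults are calibrated jointly for two
  constraints: typical curves stay within 3 normative SDs of the
  rescaled norms (otherwise the study's own outlier rule would discard
  legitimate synthetic participants; the default configuration excludes
  about 5%, close to the study's 5.7%), and the fitted group-level
  parameters sit interior to their truncation bounds, where the
  posterior geometry is sampleable.
* **Ratings.** `clamp(f(x) + Normal(0, 0.05), 0, 1)`. Additive
  Gaussian noise matches the inference model's likelihood; the default
  SD of 0.05 keeps boundary censoring negligible. The generator also
  composes the true slope as `B_i = 0.1 * numbing_z_i + b_i`, the
  reported magnitude of the numbing association.
* The ground-truth table is written to a separate file and never read
  by the inference stages.

What the generator does **not** emulate: attention-check behaviour,
reaction times, arousal, trauma-specific content, and rater
idiosyncrasies beyond additive Gaussian noise. Passing recovery tests
on these data shows the pipeline is correct and the models behave as
specified; it does not certify the substantive conclusions on real
ratings.

## Identifiability of the Hill slope — an honest account

A central finding of the package's own simulation work: on a stimulus
window of 1.33–5, the 5-PL Hill slope is only weakly identified.
Perturbing `b` by ±0.25 and re-optimizing the other four parameters
reproduces the original curve to within 0.002–0.01 rating units — for
any shape the window admits (the compensation runs mainly through the
lower asymptote `a` and the inflection scale `c`). Resolving a slope
difference of 0.25 therefore needs a per-image standard error around
0.0016 (noise SD divided by the square root of the per-group sample
size), which is what the original design achieves at n = 925/455 with
rating noise near 0.05 — and which no desk-scale configuration
reaches. The consequences, verified by simulation:

* With the participant-level SDs fixed at 1 as printed, the group mean
  `mu_b` carries a posterior SD of about `1/sqrt(n)` regardless of the
  data, and pins against its truncation bound at 1 whenever fitted
  slopes sit below about 1.5; group contrasts at desk-scale n are
  underpowered for a 0.25 gap by roughly a factor of four.
* The SD-estimating variant recovers the slope *difference* in the
  right direction with correctly ordered group posteriors, but the
  ridge keeps the intervals wide at desk scale: an 89% HPD of the
  difference typically straddles zero below a few hundred participants
  per group.
* The numbing coefficient `EN`, a population-level parameter, is
  recovered as robustly positive at 100 participants per group, but
  attenuated (posterior mean around 0.06–0.08 for a true 0.10):
  ridge-compatible, numbing-correlated shifts of the participant
  asymptotes absorb part of the coupling.
* The identifiable quantity at desk scale is the curve itself:
  posterior-mean participant curves track the generating curves to
  within well under the noise SD, and the observation noise is
  recovered accurately. The test suite asserts function-space recovery
  for this reason.

The group-contrast and numbing-recovery tests run the experiments as
specified at desk scale and report what the model can and cannot see;
convergence and model-selection behaviour of the machinery are
unaffected and are tested at full fidelity. Users applying the model to
their own data should read the slope contrast as a *joint* statement
about curve shape under the model's priors, not as an isolated curve
parameter, and should expect absolute slope values — and covariate
effects on the slope — to be attenuated unless the sample approaches
the original design's size.

## Numerical choices

* Truncated-normal layers carry their mean-dependent normalization
  terms, so hierarchical means are penalized exactly as the truncated
  densities dictate.
* The inverse-CDF non-centering clamps the mapped CDF value to
  [1e-15, 1 - 1e-15]; trajectories that reach the clamp are in the far
  tail and are rejected as divergent rather than silently distorted.
* `five_pl()` guards `x > 0`, `c > 0`, `g > 0`; the exponent in the
  likelihood kernel is capped at 690 to avoid overflow (curves beyond
  the cap have effectively reached their asymptote).
* HPD ties are broken at the lowest starting index; `ceiling(mass * n)`
  draws are always included, so the interval never undercovers by
  discretization.
* Derived per-stage seeds come from a salted Lehmer step so that every
  pipeline stage is independently reproducible below 2^31.

## Problem sizes used by the test suite

The acceptance-style tests run, as the package's chosen simulation
sizes: the convergence check on one per-group fit (the study fits each
group separately) at the full stated sampler scale — 40 participants
per group generated, 35 images, 4 chains of 1000 + 1000; the
group-contrast experiment at 5 effect seeds and 10 null seeds with
reduced draws and desk-scale groups; model selection on 2 × 15
participants and 20 images; and the numbing-association recovery at
100 participants per group with reduced draws. Oracle checks (curve
evaluation, HPD, PSIS-LOO vs exact leave-one-out, questionnaire
scoring vs brute force) run at the sizes stated in their tests.

## Limitations

* The Gaussian likelihood ignores the bounded support of VAS ratings;
  with the default noise the induced censoring is negligible, but data
  piling at 0 or 1 would need a censored or beta likelihood (out of
  scope here).
* The linear model's hierarchy is an interpretation (the comparison
  model's depth is not dictated); its priors are implemented as stated.
* LOO is computed per group on the same observations the model was fit
  to; moment-matching refits for high Pareto k are not implemented —
  flagged observations should be inspected.
* The sampler is a single-threaded R/C++ implementation; it matches
  reference posteriors on every cross-checked model but is not tuned
  for models beyond the families built here.
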