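# valtrans

Hierarchical Bayesian modelling of emotional-state transitions from
valence ratings.

## What this package is for

In studies of post-traumatic stress disorder, trauma-exposed people who
meet a probable-PTSD screening rule (PCL-5 total above 33 with DSM-5
symptom-cluster endorsement) report both emotional numbing and
hyperreactivity. A way to reconcile the two is to treat the valence
response to increasingly negative images not as a line but as a
sigmoid: a numb plateau, a transition, and a saturated response.
`valtrans` implements that analysis end to end for researchers working
with continuous visual-analog-scale (VAS) ratings of normed affective
images:

* **Screening** — PCL-5 scoring with the probable-PTSD rule
  (total > 33 plus at least 1 intrusion, 1 avoidance, 2
  cognition/mood and 2 arousal items endorsed at ≥ 2), the emotional
  numbing subscale (items 12–14), and the rating-based exclusion rule
  (more than 2 images deviating by more than 3 normative SDs).
* **Modelling** — a hierarchical five-parameter logistic (5-PL) curve

  f(x) = d + (a − d) / [1 + (x/c)^b]^g

  of rating against normative valence x, with the full truncated prior
  hierarchy (participant curves around group-level means), a linear
  comparison model, and a fixed-slope random-intercept extension
  B_i = numbing_z_i × EN + b_i regressing the Hill slope b on
  emotional numbing (optionally with age and age-interaction terms).
* **Inference** — an adaptive No-U-Turn sampler written for these
  models (compiled likelihood gradients), split-chain rank-normalized
  R-hat and bulk/tail effective sample sizes, 89%
  highest-posterior-density intervals, and group comparison by
  posterior subtraction (TEC − pPTSD) with a robustness flag.
* **Model comparison** — PSIS-LOO expected log pointwise predictive
  density with Pareto-k diagnostics, stacking / pseudo-BMA+ weights,
  and the standard rank / loo / p_loo / d_loo / weight / se table.
* **Synthetic data** — a generator reproducing the study structure
  (35 images from valence 1.33 to 5.0 plus 5 positive fillers, PCL-5
  vectors that satisfy or fail the screening rule by construction,
  curves with a group slope difference and a numbing–slope coupling)
  so every stage is testable without the undeposited study data.

## Worked example

Generate a small synthetic study, screen it, and fit the 5-PL model:

```r
library(valtrans)

norms <- generate_norms(n_images = 35, n_positive = 5, seed = 1)
gen   <- generator_config(n_per_group = 10, seed = 2)
sim   <- generate_participants(gen, norms)

# screening: groups and numbing from the questionnaires
diagnoses <- score_pcl5_table(sim$questionnaires)
table(diagnoses$group)
#>
#> pPTSD   TEC
#>    10    10

# positive images out, then fit the hierarchical 5-PL model
norms_neg <- filter_positive_images(norms)
ratings   <- sim$ratings[sim$ratings$image_id %in% norms_neg$image_id, ]
fit <- fit_model(build_5pl_model(ratings, norms_neg),
                 sampler_config(draws = 400, tune = 400, chains = 2,
                                seed = 3))
#> Warning: convergence bar not met for 108 parameter(s):
#>   max rhat 1.0825, min bulk ESS 22
fit
#> posterior_draws: model 'fivepl', 2 chains x 400 draws, 108 parameters
#>   max rhat 1.0825, min bulk ESS 22

# group-level posterior summary of the Hill slope
mu_b <- extract_draws(fit, "mu_b")
round(c(mean = mean(mu_b), hpd(mu_b, 0.89)), 3)
#>  mean
#> 1.205 1.004 1.428
```

The printed numbers are what this exact code produces: the screening
rule reproduces the intended group labels, the fit reports its
convergence summary (and warns, correctly, that two short demo chains
do not meet the R-hat/ESS bar — the full-scale settings in
`sampler_config()`'s defaults do the real work), and the 89% HPD
interval of the group-level slope is given on the model's own scale. Two groups are compared by fitting
each separately and calling `compare_groups(fit_tec, fit_pptsd,
c("mu_a", "mu_b", "mu_c", "mu_d", "mu_g"))`, which returns the TEC −
pPTSD difference, its 89% HPD and a `robust` flag per parameter;
`compute_loo()` and `compare_models()` produce the model-comparison
table. `run_pipeline()` chains all stages (generate/load → screen →
filter → fit → compare → LOO) with per-stage seeds, persisted
intermediates and a checksummed manifest.

A note for users: the package's own simulation work (see the methods
vignette) shows that the 5-PL Hill slope is only weakly identified on a
1.33–5 valence window — curves with slopes differing by ±0.25 agree to
within ~0.01 rating units — so slope contrasts should be read as joint
statements about curve shape under the model's priors, and absolute
slope values should not be over-interpreted at small sample sizes.

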