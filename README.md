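# thiodose

Bayesian individualized dosing of 6-mercaptopurine (6-MP).

6-MP is a mainstay of pediatric leukemia maintenance and of inflammatory
bowel disease therapy, but its effect is carried by the downstream metabolite
6-thioguanine nucleotide (6-TGN), whose red-blood-cell concentration must be
held inside a therapeutic window (235–400 pmol/8×10⁸ RBCs) to balance
efficacy against myelotoxicity. Conversion of 6-MP to 6-TGN is throttled by
the polymorphic enzyme TPMT, so the same standard dose leaves some patients
under-treated and pushes others toward toxicity. `thiodose` provides the
complete model-based workflow for tailoring the daily dose to a patient:

* a mechanistic three-state model of 6-MP metabolism

  $$\dot x_g = -k_{ab} x_g + d(t), \qquad
    \dot x_c = k_{ab} x_g - k_{el} x_c - \tfrac{k_{cm} x_c}{K + x_c}, \qquad
    \dot x_m = \nu_{cm}\tfrac{k_{cm} x_c}{K + x_c} - k_{me} x_m$$

  with the TPMT activity link $k_{cm} = k_{cm,max}(1 - e/e_{max})$;
* per-patient estimation from sparse 6-TGN samples — maximum likelihood,
  Metropolis–Hastings MCMC, and a Gaussian variational approximation, all on
  log-parameters under a moment-matched lognormal population prior;
* pooled **population priors** and TPMT-activity **group priors** (mixtures
  of patient posteriors weighted by data quantity);
* Sobol total-sensitivity **model reduction** with the probabilistic
  fixing-error bound $(1 + 1/\varepsilon)S_T$ (multiplier 21 at
  $\varepsilon = 0.05$) and the 2%-of-maximum partition rule;
* robust **D-optimal selection of the blood-sampling day** by maximizing
  expected Fisher information over the population prior;
* robust **model-predictive control** of the daily dose (15-day blocks,
  75-day horizon, box and slew constraints, 50-draw sample-average cost)
  with a receding-horizon closed loop that re-estimates the patient after
  each measurement;
* a **virtual-patient generator** emulating three literature-style cohorts
  (23 sparse patients / 8 dense patients / 102 paired TPMT–6-TGN
  measurements) so that the entire chain is testable without clinical data.

## Worked example

A population-mean patient on the standard 113 pmol/day oral dose plateaus at
the centre of the therapeutic window:

```r
library(thiodose)
truth <- pk_params(k_ab = 4.2, k_el = 3.8, k_cm = 39.4, K = 15.11, k_me = 0.08)
steady_state_tgn(truth, infusion = 113)
#> [1] 299.4261

doses <- daily_doses(113, 56)
simulate_pk(truth, doses, times = c(0, 4, 14, 35, 56))
#>   time        x_g      x_c       x_m
#> 1    0 113.000000 0.000000   0.00000
#> 2    4   1.720297 4.682281  75.23248
#> 3   14   1.720297 4.682282 186.02592
#> 4   35   1.720297 4.682282 259.58073
#> 5   56   1.720297 4.682282 273.28943
```

`x_m` is the 6-TGN concentration (pmol/8×10⁸ RBCs) sampled just before each
day's dose; it climbs over roughly five weeks toward its plateau. Fitting the
model to four noisy observations of this patient:

```r
y <- c(106.7, 162.9, 243.6, 263.5)          # measured 6-TGN at days 4,14,35,56
pat <- measurement_series("P01", c(4, 14, 35, 56), y, doses)
fit <- td_fit(pat, n_draws = 2000, seed = 42)   # MCMC under the default prior
coef(fit)["k_cm"]
#>     k_cm
#> 47.02797
```

The posterior mean conversion rate lands near the generating value 39.4, with
the remaining uncertainty quantified by `summary(fit)` (posterior SDs and 95%
highest-density intervals) and `predict(fit, interval = "band")`. The same
objects drive the rest of the pipeline:

```r
pop  <- build_population_prior(list_of_posteriors, n_points = n_obs_per_patient)
gsa  <- pk_sobol_report(pop)                  # k_cm dominates; others fixed
prof <- expected_information_profile(pop)     # information vs sampling day
t_star <- select_sampling_time(prof, 0.05)    # earliest day within 5% of max
plan <- optimize_dose(pop, control_config())  # robust MPC dose blocks
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, the error model, prior construction, the MCMC/variational
machinery, the sensitivity and design criteria, the controller, the
virtual-patient generator, and all numerical conventions and default
parameter choices, with their rationale.
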