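---
title: "Model-based individualized 6-mercaptopurine dosing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based individualized 6-mercaptopurine dosing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

6-mercaptopurine (6-MP) is a prodrug: its clinical effect is carried by the
intracellular metabolite 6-thioguanine nucleotide (6-TGN), whose level in red
blood cells must sit in a therapeutic window — commonly 235–400 pmol per
8×10⁸ RBCs — to balance efficacy against myelotoxicity. The enzyme thiopurine
methyltransferase (TPMT) diverts 6-MP away from the 6-TGN pathway, and TPMT
activity varies widely between patients, so a standard dose leaves some
patients under-treated and others at risk of toxicity. `thiodose` implements
a complete in-silico workflow for individualizing the daily 6-MP dose from
sparse 6-TGN measurements and a TPMT activity assay: a mechanistic
pharmacokinetic model, Bayesian population modelling, sensitivity-based model
reduction, optimal choice of the blood-sampling day, and robust
model-predictive dose control. Because no patient-level clinical data are
distributed with the package, every stage is exercised on virtual patients
produced by the package's own generator.

## The kinetic model

Three states: the amount of 6-MP in the gut `x_g` (pmol), in plasma `x_c`
(pmol), and the 6-TGN concentration in RBCs `x_m` (pmol/8×10⁸ RBCs):

$$
\begin{aligned}
\dot x_g &= -k_{ab}\,x_g + d(t)\\
\dot x_c &= k_{ab}\,x_g - k_{el}\,x_c - \frac{k_{cm}\,x_c}{K + x_c}\\
\dot x_m &= \nu_{cm}\frac{k_{cm}\,x_c}{K + x_c} - k_{me}\,x_m
\end{aligned}
$$

with absorption rate `k_ab` (1/day), plasma elimination `k_el` (1/day),
Michaelis–Menten conversion with maximal rate `k_cm` (pmol/day) and constant
`K` (pmol), 6-TGN elimination `k_me` (1/day), and stoichiometric yield
`nu_cm`. TPMT activity `e` (U/ml/hr) enters through the conversion rate,
`k_cm = k_{cm,max}\,(1 - e/e_{max})`: full activity suppresses the 6-TGN
pathway entirely.

Design choices:

* **Boluses are impulses.** Oral intake is fast relative to daily dynamics,
  so a dose event adds its amount to `x_g` instantaneously; the integrator
  restarts at every event. The default solver is `lsoda` (compiled
  right-hand side) at `rtol = 1e-8`, `atol = 1e-10`, both configurable.
* **`nu_cm` defaults to 1.** The yield and `k_cm` are not separately
  identifiable from `x_m` data, so the yield's units are absorbed into
  `k_cm`.
* **A fitted `k_cm` is the effective rate.** The TPMT activity link is
  applied only when a conversion rate is constructed *from* an activity
  (priors for new patients, the virtual-patient generator); it is never
  applied a second time during fitting.
* **`e_max = 30` U/ml/hr**, the top of the modelled activity range
  (7–30 U/ml/hr); `k_cm_max = 100` pmol/day, chosen so that the
  population-mean conversion rate (≈39 pmol/day) corresponds to a
  mid-range activity of ≈18 U/ml/hr through the link.
* Time is measured in days throughout; doses in pmol of 6-MP (a
  milligram-to-pmol conversion belongs to the caller; the molecular weight
  of 6-MP is 152.18 g/mol).

`steady_state_tgn()` is the closed-form companion: for a constant gut input
it solves the plasma balance quadratic and returns the implied 6-TGN
plateau. The default "standard dose" used by the generator and the
controller configuration, 113 pmol/day, was set once so that a
population-mean patient plateaus at ≈300 pmol/8×10⁸ RBCs, the centre of the
therapeutic window.

## Likelihood and priors

Observations are modelled as Gaussian around the simulated concentration
with heteroscedastic SD `sigma_add + sigma_prop * yhat` — the standard
additive-plus-proportional PK error model; both components are estimated
with the kinetic parameters, giving the seven-dimensional parameter
`(k_ab, k_el, k_cm, K, k_me, sigma_add, sigma_prop)`.

All inference runs on the log scale. The default prior is the multivariate
lognormal obtained by moment-matching literature-reported population means
(4.2, 3.8, 39.4, 15.11, 0.08) and covariance on the natural scale. The
reported covariance for `k_me` is incomplete; the package completes that row
so that `cor(k_cm, k_me) = 0.96` — the strong correlation this pair is known
to exhibit, arising because steady-state 6-TGN depends on their ratio — and
so that the matrix stays positive semi-definite (the implied
`var(k_me) = 5.0e-4`). The natural-vs-log-scale ambiguity in such reported
statistics is resolved here as: moments are on the natural scale, and the
lognormal is moment-matched to them. The residual-error prior is weak
(`sigma_add`: mean 10, SD 5 pmol/8×10⁸ RBCs; `sigma_prop`: mean 0.05,
SD 0.03).

## Posterior computation

**MCMC.** `sample_posterior_mcmc()` is an adaptive random-walk
Metropolis–Hastings sampler on log-parameters: 4 chains, 50% burn-in,
Robbins–Monro scale adaptation toward 30% acceptance, proposal covariance
re-shaped from the burn-in history, and split-R̂ reported (converged flagged
at < 1.05). By default the chains start at the posterior mode with the local
curvature as proposal shape (a Laplace initialisation); this costs a few
hundred extra model evaluations and removes most burn-in transient.
Densities are trimmed at ±6 prior log-SDs — negligible prior mass, and it
keeps the stiff solver away from absurd rate constants.

**Variational approximation.** `fit_variational()` maximizes the evidence
lower bound over full-covariance Gaussians in log-parameter space directly:
a Laplace initialisation followed by stochastic gradient ascent
(reparameterized draws with common random numbers per step, pathwise
gradients, Adam updates) over the mean and the per-coordinate scales, with
the initial correlation structure held fixed. The achieved bound is
returned; on problems with computable evidence the bound sits below the log
evidence, and when the target is exactly Gaussian the approximation matches
it. The package's correctness contract for the variational route is
agreement of its first and second moments with MCMC on the same problem —
the tests enforce means within 0.2 posterior SDs.

**Population and group priors.** Patient posteriors are pooled into the
mixture `M = Σ w_i p_i` with weights proportional to each patient's number
of data points; a multivariate normal is fitted to the pooled log draws for
use as an evaluable prior density. Group priors restrict the mixture to
patients in one half-open 2 U/ml/hr TPMT activity window (group 1:
7.01–9.00, group 2: 9.01–11.00, …, 11 groups over 7–30). The per-point
resampling multiplier (default 2000 draws per data point) affects only
Monte-Carlo resolution, not the pooled moments.

**Predictive bands and adequacy.** `predictive_band()` simulates one
trajectory per posterior draw, adds measurement noise from that draw's own
error parameters, and reports the per-time highest-density interval
(shortest window on sorted samples). The lack-of-fit check counts
observations outside a 95% band and reports
`confidence = P(Binom(n, 0.05) < n_outside)` (zero when nothing falls
outside); the model is deemed adequate when this is below 0.05. The strict
lower tail is a convention — the original test statistic behind this
adequacy measure is not fully specified in the source literature — and is
calibrated in the tests: model-generated data land inside the band at about
the nominal rate.

## Sensitivity-based model reduction

A new patient yields one or two measurements; estimating seven parameters
from them is hopeless unless most are fixed. Total-order Sobol indices of
the 6-TGN output are estimated with the Jansen formula from a Latin
hypercube base sample (default 1000), drawing each parameter independently
from the prior's lognormal marginals. The prior itself is correlated;
Sobol indices are only well-defined for independent inputs, so the
independent-marginals sampling is a deliberate divergence, and the indices
are read as a screening device, not as an exact variance decomposition.

The probabilistic fixing-error bound states that, with probability at least
`1 - ε`, the variance-normalized error from fixing a low-sensitivity
parameter at a nominal value stays below `(1 + 1/ε) S_T`; at the
conventional `ε = 0.05` the multiplier is 21 per evaluation time, and the
bound is accumulated over six representative days (1, 10, 20, 50, 75, 100).
Parameters whose cumulative bound falls below 2% of the largest are fixed at
the population mean. Among the remaining sensitive parameters, pairs with
posterior correlation above 0.9 in magnitude are redundant — the data cannot
separate them — so only the larger-error member is estimated online. On
priors built by the pipeline this reduces online estimation to `k_cm` alone,
with `k_me` absorbed through the correlation.

## Choosing the sampling day

With a single parameter left, D-optimality for one blood sample reduces to
maximizing the expected scalar information
`σ_t^{-2} (∂ŷ/∂k_cm)²` over candidate days (integer grid, default 1–100).
Output sensitivities are integrated by forward sensitivity equations
alongside the states (cross-checked against central finite differences);
the expectation is over prior draws, weighted uniformly — a new patient has
no data yet, so the likelihood weighting of the robust design degenerates
to the prior. Information accumulates toward steady state, so waiting
longest is nominally optimal; `select_sampling_time()` instead returns the
*earliest* day whose expected information is within a compromise fraction
(default 5%) of the maximum, trading a sliver of precision for a much
earlier patient-specific model. The specific chosen day depends on the
population prior at hand and is an output of the pipeline, not a constant.

## Robust model-predictive dose control

The dose is a constant daily bolus within each 15-day block (patients visit
every two weeks) over a 75-day horizon. The therapeutic-window constraint is
relaxed into a quadratic tracking cost toward the target 300 pmol/8×10⁸
RBCs, averaged over a frozen set of 50 posterior draws (sample-average
approximation; the draw set is refreshed at each visit, seeds recorded).
Constraints are boxes `0 ≤ u ≤ 2.5×` the standard dose — mirroring the
25–200% spread of individualized doses seen clinically — and per-block slew
limits of ±50% of the standard dose; window membership is checked as an
output property rather than imposed as a hard constraint. Optimization is
multi-start (3 starts) Nelder–Mead inside a log-barrier for the linear
constraints, with relative cost tolerance 1e-6; a feasible projection of the
standard dose seeds the search. The controller's inner loop simulates all
draws in one compiled fixed-step RK4 call (≥25 steps/day, raised
automatically for fast absorption rates; relative accuracy ~1e-4 against
the adaptive solver) — the cost function is evaluated hundreds of times per
optimization, which rules out an adaptive solver with event restarts there.

`closed_loop()` implements the receding horizon: optimize, apply the plan
only until the next measurement day, measure (with noise), update the
posterior by MCMC — online, only the sensitivity-selected parameter is
re-estimated, all others pinned to the population-prior mean — and
re-optimize from the current state. Because the plant responds monotonically
to dose, the controller moves the dose opposite to the concentration error:
a patient whose conversion rate is below their group's mean is under-dosed
by the group plan and the post-measurement dose rises, and conversely.

## The virtual-patient generator

The generator emulates the structure of three literature cohorts used for
this kind of population analysis:

* **D1** — 23 patients, 1–4 samples each within 56 days;
* **D2** — 8 patients, biweekly samples to day 140;
* **D3** — 102 patients with one TPMT activity and one 6-TGN value each.

Kinetic parameters are drawn from the moment-matched lognormal population
distribution. TPMT activities follow a truncated normal (mean 18, SD 5,
range 7–30 U/ml/hr) — the distribution is otherwise unspecified, and a
unimodal spread that populates all eleven activity groups is the natural
choice. For D3 the activity is drawn first and the conversion rate derived
through the link with multiplicative lognormal jitter (CV 20%), so that
within-activity-group heterogeneity exists — the phenomenon that makes
phenotype-based grouping only a prior, not an answer. For D1/D2 the
activity is back-derived from the sampled rate. Measurement noise defaults
to `sigma_add = 10` pmol/8×10⁸ RBCs and `sigma_prop = 0.05`, a realistic
assay scale; observations are floored at zero. Genotype classes follow the
10 U/ml/hr rule (below: heterozygous; at or above: homozygous-high, the
boundary resolved to the high class by convention); the low/low genotype is
not simulated. Dropout and dose interruptions are not simulated.

What the generator does *not* emulate: red-cell lifespan dynamics, the
methylated-metabolite pathway, circadian or adherence variation, body-size
dose scaling, and any pharmacodynamic (cell-count) response. Tests passing
on these virtual cohorts therefore validate the estimation and control
machinery under the model's own assumptions — they do not certify clinical
performance on real patients.

## Problem sizes and numerical choices in the tests

The test suite runs the full chain at reduced sizes chosen for a laptop-class
single core: per-patient MCMC uses 4×300 post-burn-in draws (600–1500 in the
statistically sensitive checks), Sobol screening 96–256 base samples, design
profiles 10–50 prior draws on coarse day grids, and the controller 6–50
draws. The parameter-recovery experiment uses 20 virtual patients with four
observations each, placed at days 9, 10, 55 and 56 — the greedy D-optimal
four-point design for the sensitive parameter pair under the default prior,
computed with the package's own expected-information machinery; it pairs
points on the concentration rise (which pin the conversion flux) with
points on the plateau (which pin the flux-to-elimination ratio). Degenerate inputs are handled explicitly: empty activity
groups raise an error (the online protocol falls back to the population
prior with a warning), a feasible set with empty interior returns the
projected plan, underdetermined likelihoods trigger the sparse fallback with
a warning, and solver-tolerance negative states are clamped at zero.

## Known limitations

* The MVN approximation to mixture priors discards multimodality; the raw
  mixtures are retained and used wherever only sampling is required.
* Sobol indices under the independent-marginals convention understate the
  effective redundancy of strongly correlated pairs; the partition step
  re-introduces it through the correlation pruning rule.
* The random-walk sampler is adequate for the 7-parameter posterior but
  split-R̂ above 1.05 can occur on very sparse patients; diagnostics are
  attached to every fit and should be checked before trusting a posterior.
* The lack-of-fit tail convention is one of several defensible choices; its
  calibration is demonstrated empirically in the tests.
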