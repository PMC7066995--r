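---
title: "Correcting attenuation from under-recorded diagnoses: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting attenuation from under-recorded diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diagnoses accumulate in electronic health records as a by-product of care,
not as planned measurements. For many conditions an absent diagnosis code
does not mean the condition is absent — the patient may simply never have
been diagnosed, or the diagnosis may live in free text. Treating "no code"
as "no condition" misclassifies true cases as non-cases. When the quantity
of interest is an association between two conditions, this
misclassification is (under the assumptions below) non-differential, and
its effect is systematic attenuation of the estimated association toward
the null: a naive analysis of recorded diagnoses understates how strongly
conditions are related, with confidence intervals that are narrow around
the wrong value.

`ehrmisclass` quantifies this attenuation exactly in small closed-form
scenarios, and corrects it in regression analyses by making the recording
error rates part of the model.

## Model

For conditions A, B, C with true statuses $T_A, T_B, T_C$ and recorded
statuses $D_A, D_B, D_C$, the generative model is

$$
T_B \sim \mathrm{Bern}(p_B), \quad
T_C \sim \mathrm{Bern}(p_C), \quad
T_A \mid T_B, T_C \sim \mathrm{Bern}\!\left(
  \mathrm{logit}^{-1}(\beta_0 + \beta_1 T_B + \beta_2 T_C)\right),
$$
$$
D_j \mid T_j \sim \mathrm{Bern}\!\left(s_j T_j + g_j (1 - T_j)\right),
\qquad j \in \{A, B, C\},
$$

where $s_j$ is the sensitivity of recording (probability a true condition
is coded) and $g_j$ the false-positive rate (probability of a code without
the condition). The description of the true-layer relationship as
"$\beta_0 + \beta_1 B + \beta_2 C$" is interpreted with a logit link — the
standard GLM for a binary outcome, and the only reading under which
coefficient sets like $(0.5, 8, 3)$ define probabilities at all.

Key assumptions, stated plainly:

* recording errors are independent across patients and across conditions
  given the true statuses (diagnoses "missing at random");
* error rates are non-differential: they do not depend on the other
  conditions' statuses;
* true B and C are independent Bernoulli draws (no correlation structure);
* patients with and without a recorded diagnosis do not differ
  systematically beyond their true status.

None of these are literally true in real records — missingness clusters
within patients and correlates across related conditions — and the model
should be read as a first-order correction, not a complete account of EHR
data generation.

### Marginalized likelihood

Rather than sampling the $3n$ latent indicators (as a latent-variable
Gibbs sampler would), the likelihood marginalizes them analytically. With
eight latent states and eight observable patterns, the probability of
pattern $d = (d_A, d_B, d_C)$ is an $8 \times 8$ emission matrix applied
to the latent-state distribution, and the recorded data enter only through
the 8-cell pattern table. This is a correctness-preserving reformulation
with two consequences: fit time is independent of cohort size, and the
per-iteration cost is a handful of vector operations
(`pattern_probabilities()`, `marginal_loglik()`). A property test verifies
the marginalized form against a brute-force per-patient sum over all
latent states, and a separate test verifies the whole posterior against a
JAGS fit of the same hierarchy with the latents sampled explicitly.

## Priors, and how they were chosen

The published description of this family of models does not pin down the
prior specification, so the package had to reconstruct it, and the
reconstruction is the one genuinely open design decision. Defaults:

* **Coefficients**: Student-t with 7 degrees of freedom and scale 2.5,
  independently on each $\beta$ (`beta_prior_sd`, `beta_prior_df`;
  `beta_prior_df = Inf` gives a Normal).
* **Prevalences**: flat Beta(1, 1) on $p_B, p_C$.
* **Error rates**: `misclass_mode = "fixed"` treats $(s_j, g_j)$ as known
  constants — the right choice for simulation studies where the generator's
  rates are known, and the default. `misclass_mode = "beta"` places
  Beta priors centred on the stated rates with an effective prior sample
  size `misclass_concentration`, for real analyses where the rates are
  themselves literature estimates. Both modes are first-class; nothing in
  the package silently picks one.

The coefficient prior deserves its own paragraph, because the obvious
choice fails. Under heavy under-recording the marginal likelihood
*saturates*: once $\beta_2$ is large enough that the relevant cell
probabilities are within recording noise of 1, the likelihood is nearly
flat in $\beta_2$ — a plateau stretching to infinity, exactly analogous to
separation in ordinary logistic regression. With a very diffuse prior
(e.g. Normal with sd 10) the posterior puts substantial mass on that
plateau, and the posterior median lands far above the generating value
(we measured medians near 4.6 for a generating slope of 3 at
$n = 20{,}000$, by MCMC and by independent quadrature). A tight Normal
(scale 2.5) fixes the median but truncates genuinely large effects: with a
generating slope of 8 the 97.5% quantile stops short of 8. The standard
weakly informative family for log-odds coefficients — Student-t with small
degrees of freedom and scale 2.5 — resolves the tension: the concentrated
body regularizes the plateau the same way such priors regularize
separation, while the heavy tails still reach large effects. Within that
family df 7 is used rather than df 3 because the heavier Cauchy-like tails
put more mass back on the plateau and drag medians up again. The sd-10
Normal remains available (`prior_spec(beta_prior_sd = 10,
beta_prior_df = Inf)`) for sensitivity analyses.

Even with this prior, the posterior median of a strongly attenuated slope
is right-skewed and varies noticeably across replications — intervals are
wide and honest, but point estimates inherit the plateau's weak
identification. Users comparing "the median" to a known truth should
expect replication-level spread of several tenths on the log-odds scale at
$n = 20{,}000$ under the default error rates.

## Sampler and numerical choices

* **Algorithm**: multiple-chain adaptive random-walk Metropolis on the
  unconstrained scale ($\beta$ raw; prevalences and, in beta mode, rates on
  the logit scale with the Beta log-Jacobians included). During warmup the
  global step size is tuned by Robbins–Monro toward an acceptance rate of
  0.234 and the proposal covariance is refreshed every 100 iterations from
  the accumulated history; both are frozen for the sampling phase, so
  retained draws come from a valid (non-adaptive) Metropolis kernel.
  Defaults: 4 chains, 2,000 warmup, 5,000 retained iterations.
* **Initialization**: naive logistic-regression estimates plus
  Normal(0, 0.5) jitter; prevalences at the recorded frequencies
  back-corrected through the profile, $(f - g)/(s - g)$, clipped to
  [0.01, 0.99].
* **Identifiability guard**: a profile with $s \le g$ makes the recorded
  status uninformative (label switching); fitting refuses such profiles
  unless `allow_ill_conditioned = TRUE`.
* **Intervals**: equal-tailed 95% credible intervals (not HPD), matching
  the convention of reporting "95% credibility intervals".
* **Diagnostics**: split R-hat (each chain halved) and
  autocorrelation-based ESS via `coda::effectiveSize()`, with a warning at
  R-hat > 1.05 or ESS < 100. Degenerate constant chains report ESS 0 and
  R-hat NaN/Inf rather than pretending health.
* **Quadrature oracle**: `grid_posterior_oracle()` integrates the
  $\le 3$-coefficient conditional posterior on a rectangular grid and warns
  if more than 1% of mass sits in the outermost cells. The test suite uses
  it two-pass — a coarse locate pass, then a fine grid over mean ± 6 sd —
  so the oracle stays independent of the MCMC it checks.
* **Closed-form inversion**: `corrected_association()` solves the 2×2
  linear system of the two-condition forward map; solutions marginally
  outside [0, 1] (possible when inputs are noisy estimates) are clipped
  and flagged rather than rejected.
* **AUROC**: Mann–Whitney rank statistic with midrank ties, so constant
  scores give exactly 0.5.

## The synthetic cohort generator

`generate_cohort()` reproduces the two-layer simulation design: a true
layer from the logistic model above, then recording noise per condition.
Four built-in coefficient sets (`simulation_params(1:4)`, from strong
$(0.2, 4, 3)$ to weak $(0.1, 0.6, 0.8)$) and per-condition default
profiles (A: 0.86/0.02, B: 0.65/0.08, C: 0.68/0.15) define the standard
study conditions; cohort sizes 100–20,000 are the standard grid.

Two generator parameters are **not** part of the published design and are
package choices, recorded in every grid report: the true prevalences of B
and C default to 0.3 each — a plausible primary-care level for the
commonly under-recorded conditions this model targets (under-diagnosis
rates near 50% are reported for conditions with prevalences broadly in
this range), and high enough that all eight pattern cells are well
populated at moderate $n$. B and C are generated independently because no
correlation structure was specified. Both are configurable
(`generator_config(prev_b =, prev_c =)`).

**Seeding contract**: one master integer seed; every stage (true layer,
recording noise, each grid cell, each chain) derives its own stream via
`derive_seed(master, key)` — a fixed polynomial hash modulo $2^{31}-1$ —
so no stage consumes another's stream and any stage can be reproduced in
isolation.

What the generator does *not* emulate: correlated missingness between
conditions, time (onset, diagnostic delay, registration windows),
practice-level heterogeneity in coding, differential recording by
severity. Passing tests therefore demonstrate correctness of the method
under its own assumptions, not robustness to their violation in real
records.

## The simulation harness

`run_grid()` crosses coefficient sets with cohort sizes (the full built-in
design is 4 × 6 = 24 cohorts), fits the naive and adjusted models on each,
and records estimates, intervals, coverage and widths; replications
default to 5 per cell so coverage statements are testable. Cell failures
are recorded, not fatal, and identical specs give identical reports.

One design note: when the quantity of interest is how interval width
changes with $n$, the test suite uses a paired design — each replication
generates a single 20,000-patient cohort and the smaller sizes are its
leading subsets (common random numbers). Between-cohort noise in the
plateau-dominated slope widths is large enough at 3 replications to mask
the trend at adjacent sizes; the paired comparison removes it without
touching the generative conditions.

## The multivariable case-control path

`generate_multivar()` and `fit_multivar_adjusted()` extend the correction
to $P \le 12$ binary predictors of a binary outcome in a case-control
design. Here the latent predictor layer is sampled per patient by
single-site Gibbs steps (exact full conditionals combining the prevalence
prior, the recorded-status evidence and the outcome likelihood),
interleaved with random-walk Metropolis updates of the coefficients and
conjugate Beta draws of the prevalences. The outcome is treated as
recorded without error — in a case-control design the outcome *defines*
the sampling — and intercepts are not population-interpretable, as usual
under outcome-dependent sampling. The predictor cap exists because the
Gibbs pass costs $O(nP)$ per iteration and mixing degrades as predictors
multiply; an exhaustive $2^P$ marginalization is already infeasible well
below the cap.

Generic error presets ("small" = 0.95/0.015, "large" = 0.85/0.04, applied
uniformly to all predictors) raise coefficient magnitudes monotonically —
naive < small < large on under-recorded data — while leaving the AUROC
essentially unchanged, because a uniform correction is close to a monotone
transform of the linear predictor and ROC analysis only sees ranks.
Condition-specific rates, where they exist, are the way to move
discrimination, not generic ones.

## Problem sizes in the test suite

The suite checks printed-value algebra exactly; Monte-Carlo agreement at
$10^6$ draws; generator distributional checks at $n$ = 40,000–200,000;
adjusted-model recovery on five replications at $n = 20{,}000$ with full
sampler settings; the quadrature cross-check on a 30-patient toy cohort
(prevalences fixed at truth, three free coefficients); the JAGS
cross-check at $n = 600$; and the multivariable direction check on a
1,000-patient, 8-predictor case-control cohort. These sizes were chosen so
the whole suite runs in about two minutes on one CPU while keeping every
statistical tolerance at 3–4 standard errors.

## Known limitations

* Weak identification of strong slopes under heavy under-recording: the
  posterior is right-skewed with a long flat tail; medians are
  prior-sensitive and replication-noisy even at $n = 20{,}000$. This is a
  property of the data-generating process, not of the sampler.
* The independence assumptions above; violations (correlated missingness,
  differential recording) are not modeled.
* Error rates must come from somewhere: fixed mode assumes they are known,
  beta mode assumes they are estimated with stated precision. For many
  conditions no published estimates exist.
* The multivariable path treats the outcome as exactly recorded by
  default; an outcome error profile is accepted by the generator but not
  by the fitter.
* No continuous covariates, no model comparison (WAIC/LOO), no
  gradient-based samplers.
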