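# ehrmisclass

Bayesian correction for under-recorded diagnoses in electronic health
record (EHR) data.

Many conditions — dementia, depression, anxiety, silent-onset chronic
disease — are substantially under-recorded in primary-care records: a
patient may have the condition while their record carries no diagnosis
code. When associations between conditions are estimated from recorded
diagnoses alone, this non-differential misclassification attenuates the
estimates toward the null. `ehrmisclass` implements a misclassification-
adjusted Bayesian logistic regression in which the recording error rates —
the sensitivity *s* = P(D=1 | T=1) and false-positive rate
*g* = P(D=1 | T=0) of each condition's recording — enter the model as prior
information, so that the association between the *true* (latent) statuses
can be recovered from the recorded data. It is aimed at epidemiologists and
methodologists working with routinely collected diagnosis tables.

## The model

For three related conditions A, B, C, the true layer is a logistic
regression with Bernoulli prevalence models for the predictors:

    B_i ~ Bernoulli(p_B),   C_i ~ Bernoulli(p_C)
    A_i | B_i, C_i ~ Bernoulli(logit^-1(beta0 + beta1 B_i + beta2 C_i))

and each recorded status is a noisy emission of the true one:

    D_{ij} | T_{ij} ~ Bernoulli( s_j T_{ij} + g_j (1 - T_{ij}) )

The likelihood of the recorded data marginalizes the 2^3 latent states
analytically, so the sufficient statistic is the 8-cell table of recorded
(D_A, D_B, D_C) patterns and the fit costs the same at n = 100 as at
n = 20,000. Priors: weakly informative Student-t(7, scale 2.5) on each
beta, Beta(1,1) on the prevalences, and rates either fixed at known values
or given Beta priors. Posteriors are sampled by multiple-chain adaptive
random-walk Metropolis with split-R-hat and effective-sample-size
diagnostics; a deterministic grid-quadrature integrator and a
latent-variable Gibbs sampler (JAGS) serve as independent cross-checks in
the test suite.

The package also ships:

* exact conditional-probability algebra for the two-condition scenario
  (forward attenuation map and its closed-form inversion),
* a synthetic EHR cohort generator with a hidden true layer and a recorded
  layer (the simulation-study conditions are built in),
* a simulation-grid harness (parameter recovery, coverage, interval
  widths),
* a Gibbs-within-Metropolis sampler for multivariable case-control
  analyses with per-predictor error presets and rank-based AUROC scoring,
* a command-line interface (`inst/cli/ehrmisclass`) with `box1`,
  `simulate`, `fit`, `grid` and `multivar` subcommands.

## Worked example

Attenuation, in closed form. With a true association P(A|B) = 0.6 against
P(A|¬B) = 0.2, prevalence P(B) = 0.1, and recording profiles
(s, g) = (0.60, 0.05) for A and (0.85, 0.03) for B:

```r
library(ehrmisclass)
sc <- two_condition_scenario(0.6, 0.2, 0.1,
                             misclass_profile(0.60, 0.05),
                             misclass_profile(0.85, 0.03))
observed_joint(sc)        # 0.03662  = P(D_A = 1, D_B = 1)
observed_marginal(sc)     # 0.112    = P(D_B = 1)
observed_association(sc)  # 0.3269643: the naive estimate of the 0.6
corrected_association(observed_association(sc),
                      observed_association_given_b0(sc),
                      sc$profile_a, sc$profile_b, sc$prevalence_b)
#>     p_a_given_b p_a_given_not_b
#>             0.6             0.2
```

The naive estimate 0.33 is barely half the true 0.6; inverting the forward
map recovers it exactly.

Recovery by the Bayesian model on a simulated cohort. The generator's
Simulation 1 has true log-odds (beta0, beta1, beta2) = (0.2, 4, 3) and the
standard recording profiles (A: 0.86/0.02, B: 0.65/0.08, C: 0.68/0.15):

```r
cfg    <- generator_config(simulation_params(1), n = 20000, seed = 1)
counts <- tabulate_patterns(generate_cohort(cfg))
fit_naive_lr_patterns(counts)
#> <naive_lr> maximum-likelihood logistic regression
#>              estimate         se     lower     upper
#> (Intercept) 0.3392118 0.01944020 0.3011090 0.3773146
#> d_b         0.8003031 0.03870274 0.7244457 0.8761605
#> d_c         0.5917552 0.03455758 0.5240224 0.6594881

fit_bayes_adjusted(counts, prior_spec(), mcmc_config(seed = 1))
#> <posterior_summary> 4 chains x 5000 retained draws (converged)
#>     parameter   mean median  lower  upper  rhat      ess
#>         beta0  0.243  0.242  0.166  0.321 1.013 1042.607
#>         beta1  3.723  3.445  2.664  6.807 1.030  346.914
#>         beta2  2.857  2.747  2.175  4.305 1.030  843.921
#>  logit_prev_b -0.866 -0.866 -0.920 -0.815 1.004  948.792
#>  logit_prev_c -0.839 -0.839 -0.899 -0.782 1.005 1064.519
```

The naive slopes 0.80 and 0.59 are a fraction of the true 4 and 3. The
adjusted posterior medians 3.45 and 2.75 sit near the truth and the 95%
credible intervals [2.66, 6.81] and [2.18, 4.31] cover it — wider than the
naive confidence intervals, which is the honest price of the recording
noise.

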