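# Naive logistic regression, the marginalized likelihood, the log-posterior,
# the MCMC machinery and its quadrature and diagnostics cross-checks.

test_that("single-predictor slope equals the closed-form log odds ratio", {
  # 2x2 cell counts (a, b, c, d) all positive
  a <- 17; b <- 9; cc <- 24; d <- 31 # (y=1,x=1), (y=0,x=1), (y=1,x=0), (y=0,x=0)
  y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  x <- c(rep(1, a + b), rep(0, cc + d))
  fit <- fit_naive_lr(y, x)
  expect_equal(unname(fit$coefficients[2]), log(a * d / (b * cc)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[1]), log(cc / d), tolerance = 1e-6)
  # Wald interval is estimate +/- 1.96 SE
  expect_equal(unname(fit$ci[2, 2] - fit$coefficients[2]),
               1.96 * unname(fit$se[2]), tolerance = 1e-12)
})

test_that("degenerate regressions fail loudly", {
  y <- rep(c(0, 1), 20)
  expect_error(fit_naive_lr(y, y), "separation")
  expect_error(fit_naive_lr(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_error(fit_naive_lr(y, rep(1, 40)), "constant")
})

test_that("naive regression is consistent on perfectly recorded data", {
  cfg <- generator_config(simulation_params(1), n = 20000, seed = 61,
                          profiles = rep(list(perfect_profile()), 3))
  co <- generate_cohort(cfg)
  fit <- fit_naive_lr(co$recorded_status[, "a"],
                      co$recorded_status[, c("b", "c")])
  truth <- c(0.2, 4, 3)
  for (p in 1:3) {
    expect_lt(abs(fit$coefficients[p] - truth[p]), 3 * fit$se[p])
  }
})

test_that("marginalized likelihood reduces correctly under perfect recording", {
  cfg <- generator_config(simulation_params(4), n = 400, seed = 71,
                          profiles = rep(list(perfect_profile()), 3))
  co <- generate_cohort(cfg)
  counts <- tabulate_patterns(co)
  beta <- c(0.3, 0.5, 0.9)
  prev_b <- 0.35; prev_c <- 0.25
  ll <- marginal_loglik(counts, logistic_params(0.3, 0.5, 0.9), prev_b, prev_c,
                        rep(list(perfect_profile()), 3))
  # complete-data decomposition computed independently from the raw rows
  a <- co$recorded_status[, "a"]; b <- co$recorded_status[, "b"]
  cc <- co$recorded_status[, "c"]
  eta <- beta[1] + beta[2] * b + beta[3] * cc
  ll_ref <- sum(a * eta - log1p(exp(eta))) +
    sum(dbinom(b, 1, prev_b, log = TRUE)) +
    sum(dbinom(cc, 1, prev_c, log = TRUE))
  expect_equal(ll, ll_ref, tolerance = 1e-8)
})

test_that("marginalized likelihood matches a per-patient brute-force sum", {
  cfg <- generator_config(simulation_params(3), n = 20, seed = 81)
  co <- generate_cohort(cfg)
  counts <- tabulate_patterns(co)
  beta <- c(-0.2, 1.1, 0.7)
  profs <- default_profiles()
  ll <- marginal_loglik(counts, logistic_params(-0.2, 1.1, 0.7), 0.3, 0.3, profs)

  # independent per-patient marginalization over the 8 latent states
  ll_ref <- 0
  for (i in seq_len(co$n)) {
    obs <- co$recorded_status[i, ]
    p_i <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      p_a <- plogis(beta[1] + beta[2] * b + beta[3] * cc)
      p_lat <- (if (a == 1) p_a else 1 - p_a) *
        (if (b == 1) 0.3 else 0.7) * (if (cc == 1) 0.3 else 0.7)
      em <- 1
      tr <- c(a, b, cc)
      for (j in 1:3) {
        pd <- if (tr[j] == 1) profs[[j]]$sensitivity else profs[[j]]$false_positive_rate
        em <- em * (if (obs[j] == 1) pd else 1 - pd)
      }
      p_i <- p_i + p_lat * em
    }
    ll_ref <- ll_ref + log(p_i)
  }
  expect_equal(ll, ll_ref, tolerance = 1e-10)
})

test_that("impossible patterns drive the likelihood to -Inf, not an error", {
  counts <- pattern_counts(c(`000` = 0L, `001` = 0L, `010` = 0L, `011` = 0L,
                             `100` = 5L, `101` = 0L, `110` = 0L, `111` = 0L))
  # with a zero false-positive rate for A and prevalence forced to 0, a
  # recorded A diagnosis is impossible
  profs <- list(quiet_profile(1, 0), perfect_profile(), perfect_profile())
  ll <- marginal_loglik(counts, logistic_params(-60, 0, 0), 0.5, 0.5, profs)
  expect_true(is.finite(ll)) # plogis(-60) is tiny but positive
  # at -800 the success probability underflows to exactly zero
  ll2 <- marginal_loglik(counts, logistic_params(-800, 0, 0), 0.5, 0.5, profs)
  expect_identical(ll2, -Inf)
})

test_that("log-posterior differences reduce to likelihood plus Jacobian in the flat limit", {
  counts <- toy_counts()
  prior <- prior_spec(beta_prior_sd = 1e6, beta_prior_df = Inf,
                      prevalence_prior = c(1, 1))
  s1 <- c(0.2, 1.0, 0.5, qlogis(0.3), qlogis(0.4))
  s2 <- c(-0.4, 2.0, 1.5, qlogis(0.5), qlogis(0.2))
  jac <- function(s) {
    p <- plogis(s[4:5])
    sum(log(p) + log(1 - p))
  }
  ll <- function(s) marginal_loglik(counts, logistic_params(s[1], s[2], s[3]),
                                    plogis(s[4]), plogis(s[5]),
                                    prior$misclass_values)
  lhs <- log_posterior(s1, counts, prior) - log_posterior(s2, counts, prior)
  rhs <- (ll(s1) + jac(s1)) - (ll(s2) + jac(s2))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("log-posterior is symmetric under exchanging the B and C blocks", {
  # counts symmetric under swapping the B and C bits, identical B/C profiles
  counts <- pattern_counts(c(`000` = 10L, `001` = 4L, `010` = 4L, `011` = 2L,
                             `100` = 8L, `101` = 3L, `110` = 3L, `111` = 5L))
  profs <- list(misclass_profile(0.86, 0.02), misclass_profile(0.7, 0.05),
                misclass_profile(0.7, 0.05))
  prior <- prior_spec(misclass_values = profs)
  s <- c(0.1, 1.4, 0.3, qlogis(0.2), qlogis(0.45))
  s_swap <- c(0.1, 0.3, 1.4, qlogis(0.45), qlogis(0.2))
  expect_equal(log_posterior(s, counts, prior),
               log_posterior(s_swap, counts, prior), tolerance = 1e-12)
})

test_that("log-posterior spot value matches an independent recomputation", {
  counts <- pattern_counts(c(`000` = 5L, `001` = 3L, `010` = 2L, `011` = 1L,
                             `100` = 4L, `101` = 2L, `110` = 2L, `111` = 1L))
  prior <- prior_spec(beta_prior_sd = 2.5, beta_prior_df = 7,
                      prevalence_prior = c(2, 5))
  s <- c(0.3, 0.8, -0.4, qlogis(0.25), qlogis(0.4))
  got <- log_posterior(s, counts, prior)

  # recompute the whole formula from scratch
  p <- enumerate_pattern_probs(c(0.3, 0.8, -0.4), 0.25, 0.4,
                               prior$misclass_values)
  cnt <- setNames(as.integer(counts), names(counts))
  want <- sum(cnt[names(p)] * log(p)) +
    sum(dt(c(0.3, 0.8, -0.4) / 2.5, 7, log = TRUE) - log(2.5)) +
    dbeta(0.25, 2, 5, log = TRUE) + log(0.25) + log(0.75) +
    dbeta(0.40, 2, 5, log = TRUE) + log(0.40) + log(0.60)
  expect_equal(got, want, tolerance = 1e-10)
  expect_identical(log_posterior(c(s[1:4], NA), counts, prior), -Inf)
})

test_that("beta-mode prior adds the recording-rate terms", {
  counts <- toy_counts()
  prior_f <- prior_spec(misclass_mode = "fixed")
  prior_b <- prior_spec(misclass_mode = "beta", misclass_concentration = 100)
  s <- c(0.1, 0.6, 0.8, qlogis(0.3), qlogis(0.3))
  rates <- unlist(lapply(default_profiles(), function(p)
    c(p$sensitivity, p$false_positive_rate)))
  s_b <- c(s, qlogis(rates))
  # at the prior means of the rates the likelihood parts agree
  got_diff <- log_posterior(s_b, counts, prior_b) -
    log_posterior(s, counts, prior_f)
  want_diff <- sum(vapply(seq_along(rates), function(i) {
    m <- rates[i]
    dbeta(m, m * 100, (1 - m) * 100, log = TRUE) + log(m) + log(1 - m)
  }, numeric(1)))
  expect_equal(as.numeric(got_diff), want_diff, tolerance = 1e-10)
})

test_that("adjusted fit refuses ill-conditioned profiles unless overridden", {
  counts <- toy_counts(n = 100)
  profs <- list(quiet_profile(0.4, 0.5), misclass_profile(0.65, 0.08),
                misclass_profile(0.68, 0.15))
  prior <- prior_spec(misclass_values = profs)
  mc <- mcmc_config(chains = 2, warmup_iterations = 50,
                    sampling_iterations = 60, seed = 1)
  expect_error(fit_bayes_adjusted(counts, prior, mc), "unidentifiable")
  expect_s3_class(
    suppressWarnings(fit_bayes_adjusted(counts, prior, mc,
                                        allow_ill_conditioned = TRUE)),
    "posterior_summary"
  )
})

test_that("adjusted fit is reproducible from its seed", {
  counts <- toy_counts(n = 200)
  mc <- mcmc_config(chains = 2, warmup_iterations = 150,
                    sampling_iterations = 200, seed = 99)
  f1 <- suppressWarnings(fit_bayes_adjusted(counts, prior_spec(), mc))
  f2 <- suppressWarnings(fit_bayes_adjusted(counts, prior_spec(), mc))
  expect_identical(f1$summary, f2$summary)
  mc2 <- mc; mc2$seed <- 100L
  f3 <- suppressWarnings(fit_bayes_adjusted(counts, prior_spec(), mc2))
  expect_false(identical(f1$summary$median, f3$summary$median))
})

test_that("with perfect profiles the posterior concentrates on the naive MLE", {
  cfg <- generator_config(simulation_params(4), n = 4000, seed = 301,
                          profiles = rep(list(perfect_profile()), 3))
  counts <- tabulate_patterns(generate_cohort(cfg))
  naive <- fit_naive_lr_patterns(counts)
  prior <- prior_spec(beta_prior_sd = 20, beta_prior_df = Inf,
                      misclass_values = rep(list(perfect_profile()), 3))
  fit <- suppressWarnings(fit_bayes_adjusted(
    counts, prior,
    mcmc_config(chains = 2, warmup_iterations = 600,
                sampling_iterations = 1500, seed = 31)
  ))
  for (p in 1:3) {
    expect_lt(abs(fit$summary$median[p] - naive$coefficients[p]), 0.15)
  }
})

test_that("quadrature oracle handles symmetric, refined and truncated grids", {
  # zero counts: the posterior is the prior, symmetric about zero
  zero <- pattern_counts(rep(0L, 8))
  g <- grid_posterior_oracle(zero, prior_spec(), fixed_prev = c(0.3, 0.3),
                             ranges = replicate(3, c(-12, 12), simplify = FALSE),
                             resolution = 61)
  for (p in c("beta0", "beta1", "beta2")) {
    expect_lt(abs(g[[p]]$mean), 1e-8)
    expect_equal(g[[p]]$median, 0, tolerance = 1e-8)
  }

  # doubling the resolution barely moves the posterior means
  counts <- toy_counts(n = 60)
  r <- list(c(-4, 4), c(-5, 7), c(-5, 7))
  g1 <- grid_posterior_oracle(counts, prior_spec(), c(0.3, 0.3), r, 41)
  g2 <- grid_posterior_oracle(counts, prior_spec(), c(0.3, 0.3), r, 81)
  for (p in c("beta0", "beta1", "beta2")) {
    expect_lt(abs(g1[[p]]$mean - g2[[p]]$mean), 0.05)
  }

  # ranges that clip the posterior trigger the boundary-mass warning
  expect_warning(
    grid_posterior_oracle(counts, prior_spec(), c(0.3, 0.3),
                          list(c(-0.2, 0.2), c(-0.2, 0.2), c(-0.2, 0.2)), 21),
    "outermost"
  )
})

test_that("diagnostics behave on constant, iid and divergent chains", {
  # identical constant chains: degenerate, flagged
  const <- array(1, dim = c(100, 2, 1), dimnames = list(NULL, NULL, "p"))
  d <- diagnostics(const)
  expect_true(is.nan(d$rhat))
  expect_equal(d$ess, 0)

  # independent standard-normal draws: R-hat near 1, ESS near the total
  set.seed(515)
  niter <- 1000
  iid <- array(rnorm(niter * 4), dim = c(niter, 4, 1),
               dimnames = list(NULL, NULL, "p"))
  d <- diagnostics(iid)
  expect_lt(abs(d$rhat - 1), 0.01)
  expect_lt(abs(d$ess - 4 * niter) / (4 * niter), 0.2)

  # chains stuck at different constants: R-hat explodes
  div <- array(rep(c(0, 5), each = 50), dim = c(50, 2, 1),
               dimnames = list(NULL, NULL, "p"))
  expect_gt(diagnostics(div)$rhat, 1.05)

  expect_error(diagnostics(array(0, c(50, 1, 1))), "2 chains")
  expect_error(diagnostics(array(0, c(5, 2, 1))), "10 draws")
})

test_that("the sampler's fast log-posterior equals the generic one", {
  counts <- toy_counts(n = 120)
  set.seed(77)
  for (fp in list(NULL, c(0.3, 0.3))) {
    f <- ehrmisclass:::make_log_post(counts, prior_spec(), fp)
    d <- if (is.null(fp)) 5 else 3
    for (i in 1:50) {
      s <- rnorm(d, sd = 2)
      expect_equal(f(s), log_posterior(s, counts, prior_spec(), fp),
                   tolerance = 1e-12)
    }
  }
})
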