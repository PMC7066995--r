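# Simulation-grid orchestration and the multivariable case-control stage.

#' Specification of a simulation grid
#'
#' The full published design crosses 4 true-layer parameter sets
#' ([simulation_params()]) with 6 cohort sizes (100, 500, 1,000, 5,000,
#' 10,000, 20,000) — 24 synthetic datasets. `grid_spec` selects any subset,
#' with `replications` independent cohorts per cell so coverage statements
#' are testable (the published design used one).
#'
#' @param simulation_ids Subset of 1:4.
#' @param sizes Subset of `c(100, 500, 1000, 5000, 10000, 20000)` (other
#'   positive sizes are allowed for exploration).
#' @param replications Cohorts per (simulation, size) cell.
#' @param base_seed Master seed; every cell derives its own stream.
#' @param prev_b,prev_c Generator prevalences (recorded in every report).
#' @param profiles Recording profiles used both to generate and to fit.
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(simulation_ids = 1:4,
                      sizes = c(100, 500, 1000, 5000, 10000, 20000),
                      replications = 5L, base_seed = 1L,
                      prev_b = 0.3, prev_c = 0.3,
                      profiles = default_profiles(),
                      prior = prior_spec(misclass_values = profiles),
                      mcmc = mcmc_config(seed = base_seed)) {
  if (length(simulation_ids) == 0 || !all(simulation_ids %in% 1:4)) {
    stop("`simulation_ids` must be a non-empty subset of 1:4", call. = FALSE)
  }
  if (length(sizes) == 0 || any(sizes < 1)) {
    stop("`sizes` must be non-empty positive cohort sizes", call. = FALSE)
  }
  if (replications < 1) stop("`replications` must be >= 1", call. = FALSE)
  check_profiles3(profiles)
  structure(
    list(simulation_ids = as.integer(simulation_ids),
         sizes = as.integer(sizes),
         replications = as.integer(replications),
         base_seed = as.integer(base_seed),
         prev_b = prev_b, prev_c = prev_c,
         profiles = profiles, prior = prior, mcmc = mcmc),
    class = "grid_spec"
  )
}

#' Run a simulation grid
#'
#' For every (simulation, size, replication) cell: generate a two-layer
#' cohort, fit the naive logistic regression and the misclassification-
#' adjusted Bayesian model on the recorded layer, and record estimates,
#' 95% intervals, truth coverage, interval widths and convergence flags.
#' Deterministic given the spec: each cell's seed is derived from
#' `base_seed` and the cell key. Convergence failures in individual cells
#' are recorded, not fatal.
#'
#' @param spec A [grid_spec()].
#' @param progress Emit a log line per cell.
#' @return A `grid_report` data frame: one row per (simulation, size,
#'   replication, method, parameter) with columns `estimate` (posterior
#'   median / MLE), `lower`, `upper`, `true_value`, `covered`, `width`,
#'   `converged`, plus the generator prevalences.
#' @export
run_grid <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  rows <- list()
  par_names <- c("beta0", "beta1", "beta2")
  for (sim in spec$simulation_ids) {
    truth <- as.numeric(simulation_params(sim))
    for (n in spec$sizes) {
      for (rep_i in seq_len(spec$replications)) {
        key <- sprintf("grid/sim%d/n%d/rep%d", sim, n, rep_i)
        seed <- derive_seed(spec$base_seed, key)
        if (progress) log_line("cell ", key, " seed ", seed)
        cfg <- generator_config(simulation_params(sim),
                                prev_b = spec$prev_b, prev_c = spec$prev_c,
                                profiles = spec$profiles, n = n, seed = seed)
        counts <- tabulate_patterns(generate_cohort(cfg))

        naive <- tryCatch(fit_naive_lr_patterns(counts), error = function(e) NULL)
        if (!is.null(naive)) {
          est <- unname(naive$coefficients)
          for (p in 1:3) {
            rows[[length(rows) + 1]] <- data.frame(
              simulation = sim, size = n, replication = rep_i,
              method = "naive", parameter = par_names[p],
              estimate = est[p], lower = naive$ci[p, 1], upper = naive$ci[p, 2],
              true_value = truth[p],
              covered = naive$ci[p, 1] <= truth[p] & truth[p] <= naive$ci[p, 2],
              width = naive$ci[p, 2] - naive$ci[p, 1],
              converged = naive$converged,
              prev_b = spec$prev_b, prev_c = spec$prev_c
            )
          }
        }

        cell_mcmc <- spec$mcmc
        cell_mcmc$seed <- derive_seed(seed, "mcmc")
        adj <- tryCatch(
          suppressWarnings(fit_bayes_adjusted(counts, spec$prior, cell_mcmc)),
          error = function(e) NULL
        )
        if (!is.null(adj)) {
          tab <- adj$summary
          for (p in 1:3) {
            r <- tab[tab$parameter == par_names[p], ]
            rows[[length(rows) + 1]] <- data.frame(
              simulation = sim, size = n, replication = rep_i,
              method = "adjusted", parameter = par_names[p],
              estimate = r$median, lower = r$lower, upper = r$upper,
              true_value = truth[p],
              covered = r$lower <= truth[p] & truth[p] <= r$upper,
              width = r$upper - r$lower,
              converged = isTRUE(adj$converged),
              prev_b = spec$prev_b, prev_c = spec$prev_c
            )
          }
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("grid_report", class(report))
  report
}

#' Aggregate a grid report
#'
#' Per (simulation, size, method, parameter): mean estimate, bias (mean
#' estimate minus truth), empirical coverage of the 95% intervals, and mean
#' interval width.
#'
#' @param report A `grid_report` from [run_grid()].
#' @return Data frame of aggregates, recomputable from the report rows.
#' @export
summarize_grid <- function(report) {
  if (is.null(report) || nrow(report) == 0) {
    stop("empty grid report", call. = FALSE)
  }
  agg <- stats::aggregate(
    cbind(estimate, covered, width) ~ simulation + size + method + parameter +
      true_value,
    data = report, FUN = mean
  )
  names(agg)[names(agg) == "estimate"] <- "mean_estimate"
  names(agg)[names(agg) == "covered"] <- "coverage"
  names(agg)[names(agg) == "width"] <- "mean_width"
  agg$bias <- agg$mean_estimate - agg$true_value
  agg[order(agg$simulation, agg$size, agg$method, agg$parameter),
      c("simulation", "size", "method", "parameter", "true_value",
        "mean_estimate", "bias", "coverage", "mean_width")]
}

#' Adjusted Bayesian fit for a multivariable case-control cohort
#'
#' Naive logistic regression of the outcome on the recorded predictors,
#' plus the misclassification-adjusted Bayesian fit in which each patient's
#' latent true predictor vector is sampled by single-site Gibbs steps
#' (exact full conditionals) interleaved with random-walk Metropolis
#' updates of the coefficients and conjugate Beta draws of the predictor
#' prevalences. The outcome is treated as correctly recorded (a
#' case-control design defines cases by record status); supply
#' `outcome_profile` to model outcome error as well.
#'
#' With perfect recording profiles the latent layer is pinned to the
#' recorded one and the fit reduces to ordinary Bayesian logistic
#' regression, matching the naive estimates within Monte-Carlo error.
#'
#' @param cohort An `ehr_cohort` with an outcome vector.
#' @param preset An [error_preset()] name (`"none"`, `"small"`, `"large"`),
#'   a single [misclass_profile()] applied to all predictors, or a list of
#'   per-predictor profiles.
#' @param prior A [prior_spec()]; only `beta_prior_sd` and
#'   `prevalence_prior` are used on this path.
#' @param mcmc An [mcmc_config()] (chains are run sequentially; warmup and
#'   sampling counts apply per chain).
#' @param max_predictors Guard on the number of predictors (default 12);
#'   the per-patient Gibbs pass is linear in predictors but mixing degrades
#'   and run time grows with many predictors.
#' @param outcome_profile Optional [misclass_profile()] for the outcome.
#' @return Object of class `multivar_fit`: `table` (per-term naive and
#'   adjusted estimates with 95% intervals), `prevalences` (posterior
#'   means), `draws`, `profiles`.
#' @export
fit_multivar_adjusted <- function(cohort, preset = "none",
                                  prior = prior_spec(), mcmc = mcmc_config(),
                                  max_predictors = 12L,
                                  outcome_profile = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (is.null(cohort$outcome)) {
    stop("cohort has no outcome column; the multivariable path needs a ",
         "case-control outcome", call. = FALSE)
  }
  k <- length(cohort$condition_names)
  if (k > max_predictors) {
    stop(k, " predictors exceed the cap of ", max_predictors, ": the latent ",
         "layer is sampled per patient by Gibbs steps, whose cost and mixing ",
         "scale with the number of predictors (an exhaustive 2^P ",
         "marginalization is already infeasible at this size). Reduce the ",
         "predictor set or raise `max_predictors` deliberately",
         call. = FALSE)
  }
  if (is.character(preset)) preset <- error_preset(preset)
  profiles <- if (inherits(preset, "misclass_profile")) {
    rep(list(preset), k)
  } else if (is.list(preset) && length(preset) == k) {
    preset
  } else {
    stop("`preset` must be a preset name, one profile, or one per predictor",
         call. = FALSE)
  }
  if (!is.null(outcome_profile)) {
    stop("modelling outcome recording error is not implemented on the ",
         "multivariable path; the outcome is treated as correctly recorded",
         call. = FALSE)
  }

  y <- cohort$outcome
  D <- cohort$recorded_status
  naive <- fit_naive_lr(y, D)

  n_par <- k + 1L
  par_names <- c("(Intercept)", cohort$condition_names)
  draws <- array(NA_real_,
                 dim = c(mcmc$sampling_iterations, mcmc$chains, n_par),
                 dimnames = list(NULL, NULL, par_names))
  prev_draws <- array(NA_real_,
                      dim = c(mcmc$sampling_iterations, mcmc$chains, k))
  prop_sd <- 2.5 * naive$se # per-coordinate random-walk scales
  perfect <- vapply(profiles, function(pr)
    pr$sensitivity == 1 && pr$false_positive_rate == 0, logical(1))

  for (ch in seq_len(mcmc$chains)) {
    res <- with_local_seed(
      derive_seed(mcmc$seed, paste0("multivar_chain", ch)),
      run_multivar_chain(y, D, profiles, perfect, prior, mcmc, naive, prop_sd)
    )
    draws[, ch, ] <- res$beta
    prev_draws[, ch, ] <- res$prev
  }

  post <- summarize_draws(draws)
  tab <- data.frame(
    term = par_names,
    naive_estimate = unname(naive$coefficients),
    naive_lower = naive$ci[, 1], naive_upper = naive$ci[, 2],
    adjusted_estimate = post$summary$median,
    adjusted_lower = post$summary$lower, adjusted_upper = post$summary$upper,
    rhat = post$summary$rhat, ess = post$summary$ess,
    row.names = NULL
  )
  structure(
    list(table = tab,
         prevalences = stats::setNames(apply(prev_draws, 3, mean),
                                       cohort$condition_names),
         draws = draws, profiles = profiles,
         converged = post$converged),
    class = "multivar_fit"
  )
}

#' @export
print.multivar_fit <- function(x, ...) {
  cat("<multivar_fit> naive and misclassification-adjusted estimates\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

# one Gibbs-within-Metropolis chain for the multivariable path
run_multivar_chain <- function(y, D, profiles, perfect, prior, mcmc, naive,
                               prop_sd) {
  n <- length(y)
  k <- ncol(D)
  s <- vapply(profiles, `[[`, numeric(1), "sensitivity")
  g <- vapply(profiles, `[[`, numeric(1), "false_positive_rate")
  # recorded-evidence log-odds contribution per predictor and value of D
  lo_d1 <- log(s) - log(g)         # D = 1: log P(D=1|X=1)/P(D=1|X=0)
  lo_d0 <- log(1 - s) - log(1 - g) # D = 0
  pa <- prior$prevalence_prior[1]
  pb <- prior$prevalence_prior[2]

  beta <- unname(naive$coefficients) + stats::rnorm(k + 1, 0, 0.5)
  X <- D # start the latent layer at the recorded layer
  prev <- pmin(pmax(colMeans(D), 0.02), 0.98)
  eta <- beta[1] + drop(X %*% beta[-1])
  loglik <- sum(y * eta - log1p(exp(eta)))

  warm <- mcmc$warmup_iterations
  keep <- mcmc$sampling_iterations
  out_beta <- matrix(NA_real_, keep, k + 1)
  out_prev <- matrix(NA_real_, keep, k)
  log_scale <- 0

  for (it in seq_len(warm + keep)) {
    # latent predictor layer: one vectorized single-site pass per predictor
    for (j in seq_len(k)) {
      if (perfect[j]) next
      eta0 <- eta - beta[j + 1] * X[, j]
      dl <- y * beta[j + 1] - log1p(exp(eta0 + beta[j + 1])) + log1p(exp(eta0))
      lo <- stats::qlogis(prev[j]) + ifelse(D[, j] == 1, lo_d1[j], lo_d0[j]) + dl
      X[, j] <- stats::rbinom(n, 1, stats::plogis(lo))
      eta <- eta0 + beta[j + 1] * X[, j]
    }
    loglik <- sum(y * eta - log1p(exp(eta)))

    # prevalences: conjugate Beta updates given the latent layer
    sums <- colSums(X)
    prev <- stats::rbeta(k, pa + sums, pb + n - sums)
    prev <- pmin(pmax(prev, 1e-6), 1 - 1e-6)

    # coefficients: a few random-walk Metropolis updates given the latent layer
    for (sweep in 1:2) {
      prop <- beta + exp(log_scale) * stats::rnorm(k + 1, 0, prop_sd)
      eta_p <- prop[1] + drop(X %*% prop[-1])
      loglik_p <- sum(y * eta_p - log1p(exp(eta_p)))
      lpost <- loglik + sum(beta_log_prior(beta, prior))
      lpost_p <- loglik_p + sum(beta_log_prior(prop, prior))
      acc <- min(1, exp(lpost_p - lpost))
      if (stats::runif(1) < acc) {
        beta <- prop
        eta <- eta_p
        loglik <- loglik_p
      }
      if (it <= warm) {
        log_scale <- log_scale + (acc - mcmc$target_acceptance) / max(20, it)^0.6
      }
    }

    if (it > warm) {
      out_beta[it - warm, ] <- beta
      out_prev[it - warm, ] <- prev
    }
  }
  list(beta = out_beta, prev = out_prev)
}

#' Patient scores and AUROC from a fitted multivariable model
#'
#' Scores each patient by the fitted linear predictor evaluated at the
#' posterior expectation of the latent predictors:
#' score_i = intercept + sum_j coef_j q_j(D_ij), where
#' q_j(d) = P(X_j = 1 | D_j = d) by Bayes' rule from the estimated
#' prevalence and the recording profile (for the naive fit the profiles are
#' perfect and the score is the usual linear predictor). AUROC is the
#' Mann-Whitney rank statistic with midrank ties, so identical scores for
#' everyone give exactly 0.5.
#'
#' @param cohort An `ehr_cohort` with an outcome.
#' @param fit A `multivar_fit`, or a coefficient vector
#'   `c(intercept, coef_1, ..., coef_k)`.
#' @param profiles Per-predictor profiles used in the fit (taken from a
#'   `multivar_fit` automatically); use perfect profiles for a naive score.
#' @param prevalences Estimated predictor prevalences (from the fit if
#'   omitted; recorded frequencies back-corrected otherwise).
#' @param method `"adjusted"` or `"naive"`: which estimates of a
#'   `multivar_fit` to score with.
#' @return List with `scores` (length n) and `auroc`.
#' @export
score_and_auroc <- function(cohort, fit, profiles = NULL, prevalences = NULL,
                            method = c("adjusted", "naive")) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  method <- match.arg(method)
  y <- cohort$outcome
  if (is.null(y)) stop("cohort has no outcome to score against", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present to compute an AUROC",
         call. = FALSE)
  }
  if (inherits(fit, "multivar_fit")) {
    coefs <- if (method == "adjusted") fit$table$adjusted_estimate
             else fit$table$naive_estimate
    if (is.null(profiles)) {
      profiles <- if (method == "adjusted") fit$profiles
                  else rep(list(perfect_profile()), ncol(cohort$recorded_status))
    }
    if (is.null(prevalences)) prevalences <- fit$prevalences
  } else {
    coefs <- as.numeric(fit)
    if (is.null(profiles)) {
      profiles <- rep(list(perfect_profile()), ncol(cohort$recorded_status))
    }
  }
  D <- cohort$recorded_status
  k <- ncol(D)
  if (length(coefs) != k + 1) {
    stop("coefficient vector must be intercept plus one slope per predictor",
         call. = FALSE)
  }
  if (is.null(prevalences)) prevalences <- colMeans(D)
  scores <- rep(coefs[1], nrow(D))
  for (j in seq_len(k)) {
    sj <- profiles[[j]]$sensitivity
    gj <- profiles[[j]]$false_positive_rate
    pj <- prevalences[j]
    # q_j(d) = P(X_j = 1 | D_j = d)
    pd1 <- pj * sj + (1 - pj) * gj
    q1 <- if (pd1 > 0) pj * sj / pd1 else 0
    pd0 <- 1 - pd1
    q0 <- if (pd0 > 0) pj * (1 - sj) / pd0 else 0
    scores <- scores + coefs[j + 1] * ifelse(D[, j] == 1, q1, q0)
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  auroc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(scores = scores, auroc = auroc)
}

#' Write / read a report or coefficient table
#'
#' Lossless round trip of any report data frame to CSV or JSON.
#'
#' @param x Data frame (e.g. a `grid_report` or a `multivar_fit$table`).
#' @param path Output / input file path.
#' @param format `"csv"` or `"json"`.
#' @return `write_report` returns `path` invisibly; `read_report` the data
#'   frame.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
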