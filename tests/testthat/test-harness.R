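# Grid orchestration, multivariable case-control fitting, AUROC scoring and
# report round trips. MCMC settings here are deliberately small: these tests
# check plumbing and direction, not posterior accuracy.

tiny_mcmc <- function(seed = 1) {
  mcmc_config(chains = 2, warmup_iterations = 150, sampling_iterations = 250,
              seed = seed)
}

test_that("the full published grid processes all 24 cohorts", {
  spec <- grid_spec(simulation_ids = 1:4,
                    sizes = c(100, 500, 1000, 5000, 10000, 20000),
                    replications = 1, base_seed = 5, mcmc = tiny_mcmc())
  report <- suppressWarnings(run_grid(spec))
  cells <- unique(report[, c("simulation", "size", "replication")])
  expect_equal(nrow(cells), 24L)
  expect_setequal(unique(report$method), c("naive", "adjusted"))
  # one row per cell, method and parameter
  expect_equal(nrow(report), 24L * 2L * 3L)
  expect_true(all(report$covered == (report$lower <= report$true_value &
                                       report$true_value <= report$upper)))
  expect_true(all(report$prev_b == 0.3))
})

test_that("grid runs are deterministic in their spec", {
  spec <- grid_spec(simulation_ids = 1, sizes = c(200, 1000), replications = 2,
                    base_seed = 77, mcmc = tiny_mcmc(77))
  r1 <- suppressWarnings(run_grid(spec))
  r2 <- suppressWarnings(run_grid(spec))
  expect_identical(r1, r2)
})

test_that("adjusted intervals narrow between the smallest and largest size", {
  spec <- grid_spec(simulation_ids = 1, sizes = c(100, 20000), replications = 1,
                    base_seed = 13,
                    mcmc = mcmc_config(chains = 2, warmup_iterations = 500,
                                       sampling_iterations = 900, seed = 13))
  report <- suppressWarnings(run_grid(spec))
  adj <- report[report$method == "adjusted", ]
  w_small <- mean(adj$width[adj$size == 100])
  w_large <- mean(adj$width[adj$size == 20000])
  expect_lt(w_large, w_small)
})

test_that("interval coverage is calibrated under the correctly specified model", {
  # perfect recording, so the adjusted model is exactly the data-generating
  # model: pooled 95% interval coverage should sit near 95%
  perfect <- rep(list(perfect_profile()), 3)
  spec <- grid_spec(simulation_ids = 4, sizes = 5000, replications = 8,
                    base_seed = 21, profiles = perfect,
                    prior = prior_spec(misclass_values = perfect),
                    mcmc = mcmc_config(chains = 2, warmup_iterations = 400,
                                       sampling_iterations = 800, seed = 21))
  report <- suppressWarnings(run_grid(spec))
  adj <- report[report$method == "adjusted", ]
  n_int <- nrow(adj)
  cov <- mean(adj$covered)
  expect_gte(cov, 0.95 - 3 * sqrt(0.95 * 0.05 / n_int))
})

test_that("grid aggregates are recomputable arithmetic", {
  rep1 <- data.frame(simulation = 1, size = 100, replication = 1:2,
                     method = "adjusted", parameter = "beta2",
                     estimate = c(2.5, 3.5), lower = c(2, 3), upper = c(3, 4),
                     true_value = 3, covered = c(TRUE, FALSE),
                     width = c(1, 1), converged = TRUE,
                     prev_b = 0.3, prev_c = 0.3)
  agg <- summarize_grid(rep1)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$mean_estimate, 3.0)
  expect_equal(agg$bias, 0.0)
  expect_equal(agg$coverage, 0.5)
  expect_equal(agg$mean_width, 1.0)

  # single-record report: aggregates equal the record
  agg1 <- summarize_grid(rep1[1, ])
  expect_equal(agg1$mean_estimate, 2.5)
  expect_equal(agg1$coverage, 1.0)

  # no interval covering the truth
  rep0 <- rep1
  rep0$covered <- FALSE
  expect_equal(summarize_grid(rep0)$coverage, 0)

  expect_error(summarize_grid(rep1[0, ]), "empty")
})

test_that("with no recording error the multivariable fit matches the naive one", {
  cfg <- multivar_config(prevalences = c(0.3, 0.2, 0.4),
                         coefficients = c(1, -0.8, 0.5), intercept = -0.5,
                         profiles = perfect_profile(),
                         n_cases = 400, n_controls = 400, seed = 91)
  co <- generate_multivar(cfg)
  fit <- suppressWarnings(fit_multivar_adjusted(
    co, preset = "none",
    mcmc = mcmc_config(chains = 2, warmup_iterations = 300,
                       sampling_iterations = 700, seed = 91)
  ))
  expect_lt(max(abs(fit$table$adjusted_estimate - fit$table$naive_estimate)),
            0.2)
})

test_that("the multivariable path agrees with the three-condition path", {
  # one noisy predictor, outcome recorded exactly: recode as a
  # three-condition cohort with a perfectly recorded dummy C
  prof_x <- error_preset("large")
  cfg <- multivar_config(prevalences = 0.3, coefficients = 1.5, intercept = -1,
                         profiles = prof_x, n_cases = 1500, n_controls = 1500,
                         seed = 111)
  co <- generate_multivar(cfg)
  mv <- suppressWarnings(fit_multivar_adjusted(
    co, preset = prof_x,
    mcmc = mcmc_config(chains = 2, warmup_iterations = 500,
                       sampling_iterations = 1200, seed = 7)
  ))

  set.seed(222)
  dummy_c <- rbinom(co$n, 1, 0.5)
  rec3 <- cbind(co$outcome, co$recorded_status[, 1], dummy_c)
  co3 <- new_cohort(rec3, condition_names = c("a", "b", "c"))
  profs3 <- list(perfect_profile(), prof_x, perfect_profile())
  fit3 <- suppressWarnings(fit_bayes_adjusted(
    tabulate_patterns(co3),
    prior_spec(misclass_values = profs3),
    mcmc_config(chains = 2, warmup_iterations = 800,
                sampling_iterations = 2000, seed = 8)
  ))
  slope_mv <- mv$table$adjusted_estimate[2]
  slope_3c <- fit3$summary$median[fit3$summary$parameter == "beta1"]
  expect_lt(abs(slope_mv - slope_3c), 0.25)
})

test_that("predictor caps and missing outcomes are rejected", {
  co <- new_cohort(matrix(rbinom(20 * 13, 1, 0.5), 20, 13))
  expect_error(fit_multivar_adjusted(co), "outcome")
  co2 <- new_cohort(matrix(rbinom(20 * 13, 1, 0.5), 20, 13),
                    outcome = rep(c(0, 1), 10))
  expect_error(fit_multivar_adjusted(co2), "cap of 12")
})

test_that("AUROC follows the midrank convention", {
  co <- new_cohort(matrix(c(1, 1, 0, 0), 4, 1), outcome = c(1, 1, 0, 0))
  # identical scores for everyone: exactly one half
  res <- score_and_auroc(co, c(0.7, 0), method = "naive")
  expect_equal(res$auroc, 0.5)
  # perfectly separating scores
  res <- score_and_auroc(co, c(0, 3), method = "naive")
  expect_equal(res$auroc, 1.0)
  # one class absent
  co1 <- new_cohort(matrix(c(1, 0), 2, 1), outcome = c(1, 1))
  expect_error(score_and_auroc(co1, c(0, 1)), "class")
})

test_that("rank-based AUROC matches an established implementation", {
  set.seed(33)
  n <- 300
  x <- matrix(rbinom(n * 2, 1, 0.4), n, 2)
  y <- rbinom(n, 1, plogis(-0.3 + x %*% c(1, -0.6)))
  co <- new_cohort(x, outcome = y)
  res <- score_and_auroc(co, c(-0.3, 1, -0.6), method = "naive")
  ref <- as.numeric(pROC::auc(pROC::roc(y, res$scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(res$auroc, ref, tolerance = 1e-12)
})

test_that("reports round-trip through CSV and JSON", {
  rep1 <- data.frame(simulation = c(1L, 1L, 2L, 2L), size = c(100L, 100L, 500L, 500L),
                     replication = 1L, method = c("naive", "adjusted"),
                     parameter = "beta1",
                     estimate = c(0.91, 3.9, 0.88, 4.1),
                     lower = c(0.8, 2.8, 0.7, 3.0),
                     upper = c(1.0, 8.3, 1.0, 8.8),
                     true_value = 4, covered = c(FALSE, TRUE, FALSE, TRUE),
                     width = c(0.2, 5.5, 0.3, 5.8), converged = TRUE,
                     prev_b = 0.3, prev_c = 0.3)
  pcsv <- withr::local_tempfile(fileext = ".csv")
  pjson <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, pcsv, "csv")
  write_report(rep1, pjson, "json")
  back_csv <- read_report(pcsv, "csv")
  back_json <- read_report(pjson, "json")
  expect_equal(back_csv, as.data.frame(rep1), ignore_attr = TRUE)
  expect_equal(back_json, as.data.frame(rep1), ignore_attr = TRUE)
  expect_equal(back_csv, back_json, ignore_attr = TRUE)

  # empty report: a valid header-only CSV
  write_report(rep1[0, ], pcsv, "csv")
  expect_equal(nrow(read_report(pcsv, "csv")), 0L)
  expect_equal(names(read_report(pcsv, "csv")), names(rep1))
})
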