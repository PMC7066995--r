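#' Synthetic EHR cohort with a hidden true layer and a recorded layer
#'
#' A cohort holds, for `n` patients and a set of named conditions, the
#' recorded diagnostic status (what an EHR would show) and — for simulated
#' data — the hidden true condition status. Real-data cohorts have no true
#' layer. Multivariable case-control cohorts additionally carry a binary
#' outcome vector.
#'
#' @param recorded n x k 0/1 matrix of recorded diagnoses.
#' @param true n x k 0/1 matrix of true statuses, or `NULL`.
#' @param condition_names Character vector of length k.
#' @param outcome Optional 0/1 outcome vector of length n (case-control
#'   designs).
#' @param outcome_name Label for the outcome.
#' @return An object of class `ehr_cohort`.
#' @export
new_cohort <- function(recorded, true = NULL, condition_names = colnames(recorded),
                       outcome = NULL, outcome_name = "outcome") {
  recorded <- as.matrix(recorded)
  if (is.null(condition_names)) {
    condition_names <- paste0("cond_", seq_len(ncol(recorded)))
  }
  if (!all(recorded %in% c(0, 1))) {
    stop("recorded statuses must be 0/1", call. = FALSE)
  }
  if (!is.null(true)) {
    true <- as.matrix(true)
    if (!identical(dim(true), dim(recorded))) {
      stop("true and recorded layers must share their shape", call. = FALSE)
    }
    if (!all(true %in% c(0, 1))) stop("true statuses must be 0/1", call. = FALSE)
    colnames(true) <- condition_names
  }
  if (!is.null(outcome)) {
    if (length(outcome) != nrow(recorded) || !all(outcome %in% c(0, 1))) {
      stop("`outcome` must be a 0/1 vector with one entry per patient",
           call. = FALSE)
    }
  }
  colnames(recorded) <- condition_names
  structure(
    list(condition_names = condition_names,
         true_status = true,
         recorded_status = recorded,
         outcome = outcome,
         outcome_name = outcome_name,
         n = nrow(recorded)),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, %d conditions (%s)%s%s\n",
              x$n, length(x$condition_names),
              paste(x$condition_names, collapse = ", "),
              if (is.null(x$true_status)) ", recorded layer only"
              else ", true + recorded layers",
              if (is.null(x$outcome)) ""
              else sprintf(", outcome `%s` (%d cases)", x$outcome_name,
                           sum(x$outcome))))
  invisible(x)
}

#' Configuration of the three-condition cohort generator
#'
#' Bundles everything the generator needs: the true-layer regression
#' parameters, the true prevalences of B and C, per-condition recording
#' profiles, the cohort size and the master seed. The prevalences of B and C
#' are free parameters of the generator (they are not part of the published
#' simulation design); the default 0.3 is a plausible primary-care level for
#' commonly under-recorded conditions and is always echoed in reports.
#'
#' @param params [logistic_params()] for the true layer.
#' @param prev_b,prev_c True prevalences of conditions B and C.
#' @param profiles List of three [misclass_profile()] (A, B, C); defaults to
#'   [default_profiles()].
#' @param n Number of patients (>= 1).
#' @param seed Master integer seed; stage streams are derived from it with
#'   [derive_seed()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(params, prev_b = 0.3, prev_c = 0.3,
                             profiles = default_profiles(), n, seed = 1L) {
  check_probability(prev_b, "prev_b")
  check_probability(prev_c, "prev_c")
  check_profiles3(profiles)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  beta <- as.numeric(params)
  if (length(beta) != 3L || any(!is.finite(beta))) {
    stop("`params` must hold three finite coefficients", call. = FALSE)
  }
  structure(
    list(params = logistic_params(beta[1], beta[2], beta[3]),
         prev_b = prev_b, prev_c = prev_c,
         profiles = profiles, n = as.integer(n), seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate the hidden true-status layer
#'
#' Draws, for each patient, true B ~ Bernoulli(`prev_b`) and true C ~
#' Bernoulli(`prev_c`) independently, then true A ~
#' Bernoulli(inverse-logit(beta0 + beta1 B + beta2 C)). Fully reproducible
#' from the config seed (stream key `"generate_true"`).
#'
#' @param config A [generator_config()].
#' @return An `ehr_cohort` whose recorded layer equals the true layer (no
#'   recording noise has been applied yet).
#' @export
generate_true <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  beta <- as.numeric(config$params)
  with_local_seed(derive_seed(config$seed, "generate_true"), {
    b <- stats::rbinom(n, 1, config$prev_b)
    cc <- stats::rbinom(n, 1, config$prev_c)
    a <- stats::rbinom(n, 1, stats::plogis(beta[1] + beta[2] * b + beta[3] * cc))
    true <- cbind(a = a, b = b, c = cc)
    new_cohort(recorded = true, true = true, condition_names = c("a", "b", "c"))
  })
}

#' Apply recording noise to a cohort's true layer
#'
#' Replaces the recorded layer: for condition j,
#' D_ij ~ Bernoulli(sensitivity_j) when T_ij = 1 and
#' D_ij ~ Bernoulli(false_positive_rate_j) when T_ij = 0, independently
#' across patients and conditions.
#'
#' @param cohort An `ehr_cohort` with a true layer.
#' @param profiles One [misclass_profile()] per condition.
#' @param seed Integer seed for the noise stream.
#' @return The cohort with both layers populated.
#' @export
apply_misclassification <- function(cohort, profiles, seed) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (is.null(cohort$true_status)) {
    stop("cohort has no true layer to misclassify", call. = FALSE)
  }
  k <- length(cohort$condition_names)
  if (length(profiles) != k) {
    stop("need one profile per condition (", k, ")", call. = FALSE)
  }
  for (j in seq_len(k)) check_profile(profiles[[j]], paste0("profiles[[", j, "]]"))
  true <- cohort$true_status
  with_local_seed(as.integer(seed), {
    rec <- matrix(0L, nrow(true), k)
    for (j in seq_len(k)) {
      s <- profiles[[j]]$sensitivity
      g <- profiles[[j]]$false_positive_rate
      rec[, j] <- stats::rbinom(nrow(true), 1, ifelse(true[, j] == 1, s, g))
    }
    new_cohort(recorded = rec, true = true,
               condition_names = cohort$condition_names,
               outcome = cohort$outcome, outcome_name = cohort$outcome_name)
  })
}

#' Generate a complete two-layer synthetic cohort
#'
#' Composition of [generate_true()] and [apply_misclassification()]; a
#' single master seed in the config derives both stage streams (keys
#' `"generate_true"` and `"misclass"`), so either stage is individually
#' reproducible.
#'
#' @param config A [generator_config()].
#' @return An `ehr_cohort` with true and recorded layers.
#' @examples
#' cfg <- generator_config(simulation_params(1), n = 500, seed = 42)
#' generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  cohort <- generate_true(config)
  apply_misclassification(cohort, config$profiles,
                          derive_seed(config$seed, "misclass"))
}

#' Counts of the eight recorded-diagnosis patterns
#'
#' Tabulates the recorded (D_A, D_B, D_C) patterns of a three-condition
#' cohort. The eight counts are the sufficient statistic for the
#' marginalized likelihood of [fit_bayes_adjusted()], which makes its run
#' time independent of the cohort size.
#'
#' @param cohort An `ehr_cohort` with exactly three conditions.
#' @return Object of class `pattern_counts`: integer vector of length 8
#'   named as in [pattern_probabilities()], with attribute `n`.
#' @export
tabulate_patterns <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (length(cohort$condition_names) != 3L) {
    stop("pattern tabulation is defined for exactly three conditions; ",
         "for more predictors use the multivariable path ",
         "(fit_multivar_adjusted)", call. = FALSE)
  }
  rec <- cohort$recorded_status
  idx <- 4 * rec[, 1] + 2 * rec[, 2] + rec[, 3] + 1
  counts <- tabulate(idx, nbins = 8)
  pattern_counts(stats::setNames(as.integer(counts), pattern_labels()))
}

#' Construct a pattern-count object
#'
#' @param counts Named (or pattern-ordered) non-negative integer vector of
#'   length 8; names follow [pattern_probabilities()].
#' @return Object of class `pattern_counts`.
#' @export
pattern_counts <- function(counts) {
  if (length(counts) != 8L || any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be 8 non-negative integers", call. = FALSE)
  }
  lbl <- pattern_labels()
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), lbl)) {
      stop("count names must be the 8 patterns ", paste(lbl, collapse = ", "),
           call. = FALSE)
    }
    counts <- counts[lbl]
  } else {
    names(counts) <- lbl
  }
  structure(as.integer(counts), names = lbl, n = sum(counts),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("<pattern_counts> n =", attr(x, "n"), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Configuration of the multivariable case-control generator
#'
#' Latent binary predictors X_j ~ Bernoulli(`prevalences[j]`) independently;
#' binary outcome Y ~ Bernoulli(inverse-logit(intercept + sum coef_j X_j));
#' recorded predictors D_j generated from X_j through per-predictor
#' profiles. Patients are rejection-sampled until `n_cases` cases and
#' `n_controls` controls are collected (a case-control design: the outcome
#' is defined by record status and recorded without error unless
#' `outcome_profile` is supplied).
#'
#' @param prevalences Probability vector, one per predictor.
#' @param coefficients Log-odds coefficient vector, one per predictor.
#' @param intercept Log-odds intercept.
#' @param profiles One [misclass_profile()] per predictor, or a single
#'   profile recycled to all predictors.
#' @param n_cases,n_controls Target counts.
#' @param seed Master integer seed.
#' @param outcome_profile Optional [misclass_profile()] for the outcome
#'   itself (default: outcome recorded exactly).
#' @param predictor_names Optional labels.
#' @return An object of class `multivar_config`.
#' @export
multivar_config <- function(prevalences, coefficients, intercept = 0,
                            profiles, n_cases, n_controls, seed = 1L,
                            outcome_profile = NULL, predictor_names = NULL) {
  k <- length(prevalences)
  if (length(coefficients) != k) {
    stop("`prevalences` and `coefficients` must have equal length", call. = FALSE)
  }
  for (i in seq_len(k)) check_probability(prevalences[i], paste0("prevalences[", i, "]"))
  if (inherits(profiles, "misclass_profile")) profiles <- rep(list(profiles), k)
  if (length(profiles) != k) {
    stop("need one profile per predictor (or a single profile to recycle)",
         call. = FALSE)
  }
  for (j in seq_len(k)) check_profile(profiles[[j]], paste0("profiles[[", j, "]]"))
  if (!is.null(outcome_profile)) check_profile(outcome_profile, "outcome_profile")
  if (n_cases < 1 || n_controls < 1) {
    stop("`n_cases` and `n_controls` must be positive", call. = FALSE)
  }
  if (is.null(predictor_names)) predictor_names <- paste0("x", seq_len(k))
  structure(
    list(prevalences = as.numeric(prevalences),
         coefficients = as.numeric(coefficients),
         intercept = as.numeric(intercept),
         profiles = profiles,
         outcome_profile = outcome_profile,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         seed = as.integer(seed),
         predictor_names = predictor_names),
    class = "multivar_config"
  )
}

#' Generate a multivariable case-control cohort
#'
#' Rejection-samples patients from the generative model of
#' [multivar_config()] until the requested numbers of cases and controls
#' are collected. Errors out if the case (or control) probability is so
#' small that the target cannot be reached within a bounded number of
#' draws.
#'
#' @param config A [multivar_config()].
#' @param max_batches Safety bound on rejection batches (each batch draws
#'   `4 * (n_cases + n_controls)` candidates).
#' @return An `ehr_cohort` with outcome vector, true and recorded predictor
#'   layers.
#' @export
generate_multivar <- function(config, max_batches = 200L) {
  stopifnot(inherits(config, "multivar_config"))
  k <- length(config$prevalences)
  need_cases <- config$n_cases
  need_ctrls <- config$n_controls
  batch <- 4L * (need_cases + need_ctrls)
  X_cases <- X_ctrls <- matrix(0L, 0, k)
  with_local_seed(derive_seed(config$seed, "multivar"), {
    for (b in seq_len(max_batches)) {
      X <- matrix(stats::rbinom(batch * k, 1, rep(config$prevalences, each = batch)),
                  batch, k)
      eta <- config$intercept + drop(X %*% config$coefficients)
      y <- stats::rbinom(batch, 1, stats::plogis(eta))
      if (!is.null(config$outcome_profile)) {
        s <- config$outcome_profile$sensitivity
        g <- config$outcome_profile$false_positive_rate
        y <- stats::rbinom(batch, 1, ifelse(y == 1, s, g))
      }
      if (nrow(X_cases) < need_cases) {
        take <- utils::head(which(y == 1), need_cases - nrow(X_cases))
        X_cases <- rbind(X_cases, X[take, , drop = FALSE])
      }
      if (nrow(X_ctrls) < need_ctrls) {
        take <- utils::head(which(y == 0), need_ctrls - nrow(X_ctrls))
        X_ctrls <- rbind(X_ctrls, X[take, , drop = FALSE])
      }
      if (nrow(X_cases) >= need_cases && nrow(X_ctrls) >= need_ctrls) break
    }
    if (nrow(X_cases) < need_cases || nrow(X_ctrls) < need_ctrls) {
      stop("could not collect ", need_cases, " cases and ", need_ctrls,
           " controls within ", max_batches, " rejection batches; the ",
           "requested class is too rare under this configuration",
           call. = FALSE)
    }
    true <- rbind(X_cases, X_ctrls)
    outcome <- c(rep(1L, need_cases), rep(0L, need_ctrls))
    # recorded predictor layer
    rec <- matrix(0L, nrow(true), k)
    for (j in seq_len(k)) {
      s <- config$profiles[[j]]$sensitivity
      g <- config$profiles[[j]]$false_positive_rate
      rec[, j] <- stats::rbinom(nrow(true), 1, ifelse(true[, j] == 1, s, g))
    }
    new_cohort(recorded = rec, true = true,
               condition_names = config$predictor_names,
               outcome = outcome, outcome_name = "case")
  })
}

#' Write / read a cohort as CSV
#'
#' Plain UTF-8 comma-separated text: a `patient_id` column, one `d_<cond>`
#' column per recorded condition, optional `t_<cond>` columns for the true
#' layer, and an outcome column (its own name) for case-control cohorts.
#'
#' @param cohort An `ehr_cohort`.
#' @param path Output / input file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `ehr_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  df <- data.frame(patient_id = seq_len(cohort$n))
  for (j in seq_along(cohort$condition_names)) {
    df[[paste0("d_", cohort$condition_names[j])]] <- cohort$recorded_status[, j]
  }
  if (!is.null(cohort$true_status)) {
    for (j in seq_along(cohort$condition_names)) {
      df[[paste0("t_", cohort$condition_names[j])]] <- cohort$true_status[, j]
    }
  }
  if (!is.null(cohort$outcome)) df[[cohort$outcome_name]] <- cohort$outcome
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param outcome_name Column treated as the outcome when reading, if
#'   present.
#' @export
read_cohort_csv <- function(path, outcome_name = "case") {
  df <- utils::read.csv(path, check.names = FALSE)
  d_cols <- grep("^d_", names(df), value = TRUE)
  if (length(d_cols) == 0) {
    stop("no recorded-status columns (d_<condition>) found in ", path,
         call. = FALSE)
  }
  conds <- sub("^d_", "", d_cols)
  rec <- as.matrix(df[, d_cols, drop = FALSE])
  t_cols <- paste0("t_", conds)
  true <- if (all(t_cols %in% names(df))) {
    as.matrix(df[, t_cols, drop = FALSE])
  } else NULL
  outcome <- if (outcome_name %in% names(df)) df[[outcome_name]] else NULL
  new_cohort(recorded = rec, true = true, condition_names = conds,
             outcome = outcome, outcome_name = outcome_name)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
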