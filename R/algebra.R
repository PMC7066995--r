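#' Two-condition misclassification scenario
#'
#' A hypothetical pair of conditions A and B where the association of
#' interest is P(A | B) versus P(A | not B), B has prevalence `prevalence_b`,
#' and each condition is imperfectly captured in the record according to its
#' [misclass_profile()]. This is the setting of the worked conditional-
#' probability example used throughout the package's documentation.
#'
#' @param p_a_given_b P(A = 1 | B = 1).
#' @param p_a_given_not_b P(A = 1 | B = 0).
#' @param prevalence_b P(B = 1).
#' @param profile_a,profile_b Recording profiles for A and B.
#' @return An object of class `two_condition_scenario`.
#' @examples
#' sc <- two_condition_scenario(0.6, 0.2, 0.1,
#'                              misclass_profile(0.6, 0.05),
#'                              misclass_profile(0.85, 0.03))
#' observed_association(sc) # attenuated well below the true 0.6
#' @export
two_condition_scenario <- function(p_a_given_b, p_a_given_not_b, prevalence_b,
                                   profile_a, profile_b) {
  check_probability(p_a_given_b, "p_a_given_b")
  check_probability(p_a_given_not_b, "p_a_given_not_b")
  check_probability(prevalence_b, "prevalence_b")
  check_profile(profile_a, "profile_a")
  check_profile(profile_b, "profile_b")
  structure(
    list(p_a_given_b = p_a_given_b,
         p_a_given_not_b = p_a_given_not_b,
         prevalence_b = prevalence_b,
         profile_a = profile_a,
         profile_b = profile_b),
    class = "two_condition_scenario"
  )
}

#' @export
print.two_condition_scenario <- function(x, ...) {
  cat(sprintf(paste0("<two_condition_scenario>\n",
                     "  P(A|B) = %g, P(A|~B) = %g, P(B) = %g\n",
                     "  A recorded with s = %g, g = %g; B with s = %g, g = %g\n"),
              x$p_a_given_b, x$p_a_given_not_b, x$prevalence_b,
              x$profile_a$sensitivity, x$profile_a$false_positive_rate,
              x$profile_b$sensitivity, x$profile_b$false_positive_rate))
  invisible(x)
}

#' Joint probability of recorded diagnoses of both conditions
#'
#' P(D_A = 1, D_B = 1): the total probability of the four latent (A, B)
#' states, each contributing
#' P(A = a | B = b) P(B = b) P(D_A = 1 | A = a) P(D_B = 1 | B = b).
#'
#' @param scenario A [two_condition_scenario()].
#' @return The joint probability of a recorded diagnosis for both A and B.
#' @export
observed_joint <- function(scenario) {
  stopifnot(inherits(scenario, "two_condition_scenario"))
  sa <- scenario$profile_a$sensitivity
  ga <- scenario$profile_a$false_positive_rate
  sb <- scenario$profile_b$sensitivity
  gb <- scenario$profile_b$false_positive_rate
  pb <- scenario$prevalence_b
  p1 <- scenario$p_a_given_b
  p0 <- scenario$p_a_given_not_b
  p1 * pb * sa * sb +
    p0 * (1 - pb) * sa * gb +
    (1 - p1) * pb * ga * sb +
    (1 - p0) * (1 - pb) * ga * gb
}

#' Marginal probability of a recorded diagnosis of condition B
#'
#' P(D_B = 1) = P(B) P(D_B = 1 | B) + P(not B) P(D_B = 1 | not B).
#'
#' @inheritParams observed_joint
#' @return The marginal probability of a recorded B diagnosis.
#' @export
observed_marginal <- function(scenario) {
  stopifnot(inherits(scenario, "two_condition_scenario"))
  sb <- scenario$profile_b$sensitivity
  gb <- scenario$profile_b$false_positive_rate
  pb <- scenario$prevalence_b
  pb * sb + (1 - pb) * gb
}

#' Observed (attenuated) association between recorded diagnoses
#'
#' The naive estimate of the association between A and B that uses recorded
#' diagnoses only: P(D_A = 1 | D_B = 1) = P(D_A = 1, D_B = 1) / P(D_B = 1).
#' Under imperfect recording this lies between the true P(A | B) and the
#' null, which is the attenuation this package exists to correct.
#'
#' @inheritParams observed_joint
#' @return P(D_A = 1 | D_B = 1).
#' @export
observed_association <- function(scenario) {
  marg <- observed_marginal(scenario)
  if (marg <= 0) {
    stop("P(D_B = 1) is zero: no recorded B diagnoses are possible ",
         "under this scenario, the observed association is undefined",
         call. = FALSE)
  }
  observed_joint(scenario) / marg
}

#' Analytic correction of an observed association
#'
#' Inverts the forward misclassification map in closed form. Writing
#' q_d = P(A = 1 | D_B = d), the observed quantities satisfy
#' P(D_A = 1 | D_B = d) = s_A q_d + g_A (1 - q_d), and q_d is a mixture
#' w_d P(A | B) + (1 - w_d) P(A | not B) with weights w_d = P(B = 1 | D_B = d)
#' given by Bayes' rule from `prevalence_b` and `profile_b`. The two linear
#' equations (d = 1, 0) are solved for P(A | B) and P(A | not B).
#'
#' This closed form is the deterministic counterpart of the Bayesian
#' correction in [fit_bayes_adjusted()] and serves as its oracle in the
#' two-condition case.
#'
#' @param obs_a_given_b1 Observed P(D_A = 1 | D_B = 1).
#' @param obs_a_given_b0 Observed P(D_A = 1 | D_B = 0).
#' @param profile_a,profile_b Recording profiles; both must be
#'   well-conditioned (sensitivity > false-positive rate).
#' @param prevalence_b True prevalence P(B = 1).
#' @return Named numeric vector `c(p_a_given_b, p_a_given_not_b)`. If
#'   sampling noise in the inputs pushes a solution outside \[0, 1\] it is
#'   clipped and a warning is issued; attribute `"clipped"` records whether
#'   clipping occurred.
#' @examples
#' sc <- two_condition_scenario(0.6, 0.2, 0.1,
#'                              misclass_profile(0.6, 0.05),
#'                              misclass_profile(0.85, 0.03))
#' corrected_association(observed_association(sc),
#'                       observed_association_given_b0(sc),
#'                       sc$profile_a, sc$profile_b, sc$prevalence_b)
#' @export
corrected_association <- function(obs_a_given_b1, obs_a_given_b0,
                                  profile_a, profile_b, prevalence_b) {
  check_probability(obs_a_given_b1, "obs_a_given_b1")
  check_probability(obs_a_given_b0, "obs_a_given_b0")
  check_profile(profile_a, "profile_a")
  check_profile(profile_b, "profile_b")
  check_probability(prevalence_b, "prevalence_b")
  if (is_ill_conditioned(profile_a) || is_ill_conditioned(profile_b)) {
    stop("corrected_association requires well-conditioned profiles ",
         "(sensitivity > false_positive_rate for both conditions)",
         call. = FALSE)
  }
  sa <- profile_a$sensitivity
  ga <- profile_a$false_positive_rate
  sb <- profile_b$sensitivity
  gb <- profile_b$false_positive_rate
  pb <- prevalence_b

  # de-noise A: q_d = P(A=1 | D_B=d) from s_A q + g_A (1-q) = obs
  q1 <- (obs_a_given_b1 - ga) / (sa - ga)
  q0 <- (obs_a_given_b0 - ga) / (sa - ga)

  # weights w_d = P(B=1 | D_B=d) by Bayes' rule
  marg1 <- pb * sb + (1 - pb) * gb
  marg0 <- 1 - marg1
  if (marg1 <= 0 || marg0 <= 0) {
    stop("degenerate recorded-B distribution: P(D_B = ", if (marg1 <= 0) 1 else 0,
         ") is zero, the system is not solvable", call. = FALSE)
  }
  w1 <- pb * sb / marg1
  w0 <- pb * (1 - sb) / marg0
  if (abs(w1 - w0) < 1e-12) {
    stop("singular correction: P(B = 1 | D_B = 1) equals P(B = 1 | D_B = 0), ",
         "the recorded B diagnosis carries no information about B",
         call. = FALSE)
  }

  # solve q_d = w_d p1 + (1 - w_d) p0 for (p1, p0)
  p1 <- ((1 - w0) * q1 - (1 - w1) * q0) / (w1 - w0)
  p0 <- (w1 * q0 - w0 * q1) / (w1 - w0)

  out <- c(p_a_given_b = p1, p_a_given_not_b = p0)
  clipped <- any(out < 0 | out > 1)
  if (clipped) {
    warning("corrected association fell outside [0, 1] and was clipped; ",
            "inputs are likely noisy estimates", call. = FALSE)
    out <- pmin(pmax(out, 0), 1)
  }
  attr(out, "clipped") <- clipped
  out
}

#' Observed association conditional on an absent recorded B diagnosis
#'
#' P(D_A = 1 | D_B = 0), the companion of [observed_association()] needed by
#' the closed-form inversion.
#'
#' @inheritParams observed_joint
#' @return P(D_A = 1 | D_B = 0).
#' @export
observed_association_given_b0 <- function(scenario) {
  stopifnot(inherits(scenario, "two_condition_scenario"))
  marg0 <- 1 - observed_marginal(scenario)
  if (marg0 <= 0) {
    stop("P(D_B = 0) is zero under this scenario", call. = FALSE)
  }
  sa <- scenario$profile_a$sensitivity
  ga <- scenario$profile_a$false_positive_rate
  sb <- scenario$profile_b$sensitivity
  gb <- scenario$profile_b$false_positive_rate
  pb <- scenario$prevalence_b
  p1 <- scenario$p_a_given_b
  p0 <- scenario$p_a_given_not_b
  joint0 <- p1 * pb * sa * (1 - sb) +
    p0 * (1 - pb) * sa * (1 - gb) +
    (1 - p1) * pb * ga * (1 - sb) +
    (1 - p0) * (1 - pb) * ga * (1 - gb)
  joint0 / marg0
}

#' Logistic regression parameters on the log-odds scale
#'
#' The true-layer model for three conditions: the probability that a patient
#' truly has condition A is inverse-logit(beta0 + beta1 B + beta2 C), where B
#' and C are the patient's true statuses for the other two conditions.
#'
#' @param beta0 Intercept (log-odds of A when B = C = 0).
#' @param beta1,beta2 Log-odds increments for B and C.
#' @return Named numeric vector of class `logistic_params`.
#' @export
logistic_params <- function(beta0, beta1, beta2) {
  b <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2)
  if (!is.numeric(b) || any(!is.finite(b))) {
    stop("logistic parameters must be finite reals", call. = FALSE)
  }
  structure(b, class = c("logistic_params", "numeric"))
}

#' True-layer parameter sets of the four simulation scenarios
#'
#' The four (beta0, beta1, beta2) triplets used in the simulation study,
#' spanning strong (4, 8) to weak (0.5, 0.8) associations.
#'
#' @param id Simulation number, 1 to 4.
#' @return A [logistic_params()] vector.
#' @export
simulation_params <- function(id) {
  if (!id %in% 1:4) stop("`id` must be 1, 2, 3 or 4", call. = FALSE)
  tab <- rbind(c(0.2, 4, 3),
               c(0.5, 8, 3),
               c(0.1, 0.5, 2.6),
               c(0.1, 0.6, 0.8))
  logistic_params(tab[id, 1], tab[id, 2], tab[id, 3])
}

#' Exact probabilities of the eight recorded-diagnosis patterns
#'
#' For the three-condition model — true B ~ Bernoulli(`prev_b`), true C ~
#' Bernoulli(`prev_c`) independently, true A | B, C ~
#' Bernoulli(inverse-logit(beta0 + beta1 B + beta2 C)), and each recorded
#' status generated from the true one through its [misclass_profile()] —
#' returns P(D_A = a, D_B = b, D_C = c) for the eight binary patterns by
#' summing over the eight latent (A, B, C) states.
#'
#' These probabilities are the sufficient ingredients of the marginalized
#' likelihood used by [fit_bayes_adjusted()].
#'
#' @param params [logistic_params()] for the true layer.
#' @param prev_b,prev_c True prevalences of B and C.
#' @param profiles List of three [misclass_profile()] objects for A, B, C
#'   (in that order).
#' @return Numeric vector of length 8, named by the pattern `"<a><b><c>"`
#'   (e.g. `"101"` is D_A = 1, D_B = 0, D_C = 1); sums to 1.
#' @export
pattern_probabilities <- function(params, prev_b, prev_c, profiles) {
  check_probability(prev_b, "prev_b")
  check_probability(prev_c, "prev_c")
  check_profiles3(profiles)
  beta <- as.numeric(params)
  if (length(beta) != 3L || any(!is.finite(beta))) {
    stop("`params` must hold three finite coefficients (beta0, beta1, beta2)",
         call. = FALSE)
  }
  latent <- latent_state_probs(beta, prev_b, prev_c)
  p <- drop(emission_matrix(profiles) %*% latent)
  stats::setNames(p, pattern_labels())
}

# latent (A,B,C) state probabilities, states ordered as pattern_labels()
latent_state_probs <- function(beta, prev_b, prev_c) {
  states <- pattern_states()
  p_a <- stats::plogis(beta[1] + beta[2] * states[, 2] + beta[3] * states[, 3])
  pr <- ifelse(states[, 1] == 1, p_a, 1 - p_a) *
    ifelse(states[, 2] == 1, prev_b, 1 - prev_b) *
    ifelse(states[, 3] == 1, prev_c, 1 - prev_c)
  as.numeric(pr)
}

# 8x8 matrix E[obs, latent] = P(D = obs | T = latent), product over conditions
emission_matrix <- function(profiles) {
  states <- pattern_states()
  E <- matrix(1, 8, 8)
  for (j in 1:3) {
    s <- profiles[[j]]$sensitivity
    g <- profiles[[j]]$false_positive_rate
    # P(D_j = d | T_j = t)
    pdt <- outer(states[, j], states[, j],
                 function(d, t) ifelse(t == 1, ifelse(d == 1, s, 1 - s),
                                       ifelse(d == 1, g, 1 - g)))
    E <- E * pdt
  }
  E
}

# the 8 binary triplets (a, b, c), c varying fastest: 000, 001, ..., 111
pattern_states <- function() {
  as.matrix(expand.grid(c = 0:1, b = 0:1, a = 0:1))[, 3:1, drop = FALSE]
}

pattern_labels <- function() {
  st <- pattern_states()
  paste0(st[, 1], st[, 2], st[, 3])
}
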