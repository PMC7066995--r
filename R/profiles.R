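#' Recording-error profile for one condition
#'
#' Describes how a true condition status is captured in the record:
#' `sensitivity` is the probability that a patient with the condition has a
#' recorded diagnosis, P(D = 1 | T = 1); `false_positive_rate` is the
#' probability that a patient without the condition nevertheless has one,
#' P(D = 1 | T = 0) (i.e. 1 - specificity of recording).
#'
#' When `sensitivity <= false_positive_rate` the recorded diagnosis carries no
#' (or inverted) information about the true status: correction is
#' ill-conditioned and label switching becomes possible. The constructor
#' warns and flags the profile; see [is_ill_conditioned()].
#'
#' @param sensitivity Probability in \[0, 1\].
#' @param false_positive_rate Probability in \[0, 1\].
#' @return An object of class `misclass_profile`.
#' @examples
#' misclass_profile(0.86, 0.02) # dementia-like under-recording
#' @export
misclass_profile <- function(sensitivity, false_positive_rate) {
  check_probability(sensitivity, "sensitivity")
  check_probability(false_positive_rate, "false_positive_rate")
  ill <- sensitivity <= false_positive_rate
  if (ill) {
    warning("profile is ill-conditioned: sensitivity (", sensitivity,
            ") <= false_positive_rate (", false_positive_rate,
            "); recording is no better than chance and inversion is unstable",
            call. = FALSE)
  }
  structure(
    list(sensitivity = sensitivity,
         false_positive_rate = false_positive_rate,
         ill_conditioned = ill),
    class = "misclass_profile"
  )
}

#' @export
print.misclass_profile <- function(x, ...) {
  cat(sprintf("<misclass_profile> P(D=1|T=1) = %g, P(D=1|T=0) = %g%s\n",
              x$sensitivity, x$false_positive_rate,
              if (x$ill_conditioned) "  [ill-conditioned]" else ""))
  invisible(x)
}

#' Is a recording profile ill-conditioned?
#'
#' `TRUE` when sensitivity does not exceed the false-positive rate, in which
#' case the recorded diagnosis is uninformative about the true status.
#'
#' @param profile A [misclass_profile()].
#' @return Logical scalar.
#' @export
is_ill_conditioned <- function(profile) {
  stopifnot(inherits(profile, "misclass_profile"))
  isTRUE(profile$ill_conditioned)
}

#' Perfect-recording profile
#'
#' Sensitivity 1 and false-positive rate 0: the recorded layer equals the
#' true layer. Useful for no-error reductions.
#'
#' @return A [misclass_profile()].
#' @export
perfect_profile <- function() misclass_profile(1, 0)

#' Generic error presets for multivariable analyses
#'
#' Two generic recording-error presets applied uniformly to all predictors in
#' a multivariable analysis: `"small"` assumes sensitivity 0.95 and
#' false-positive rate 0.015; `"large"` assumes 0.85 and 0.04. `"none"` is
#' perfect recording.
#'
#' @param name One of `"none"`, `"small"`, `"large"`.
#' @return A [misclass_profile()].
#' @export
error_preset <- function(name = c("none", "small", "large")) {
  name <- match.arg(name)
  switch(name,
         none  = perfect_profile(),
         small = misclass_profile(0.95, 0.015),
         large = misclass_profile(0.85, 0.04))
}

#' Default recording-error profiles for the three-condition simulations
#'
#' The per-condition sensitivities and false-positive rates used throughout
#' the three-condition simulation study: A is recorded with sensitivity 0.86
#' and false-positive rate 0.02, B with 0.65/0.08, C with 0.68/0.15.
#'
#' @return Named list of three [misclass_profile()] objects (`a`, `b`, `c`).
#' @export
default_profiles <- function() {
  list(a = misclass_profile(0.86, 0.02),
       b = misclass_profile(0.65, 0.08),
       c = misclass_profile(0.68, 0.15))
}

# internal validation helpers ------------------------------------------------

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1], got ",
         deparse(substitute(x, env = environment())), " = ",
         paste(format(x), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_profile <- function(x, name) {
  if (!inherits(x, "misclass_profile")) {
    stop("`", name, "` must be a misclass_profile object", call. = FALSE)
  }
  invisible(x)
}

check_profiles3 <- function(profiles) {
  if (!is.list(profiles) || length(profiles) != 3L) {
    stop("`profiles` must be a list of three misclass_profile objects ",
         "(conditions A, B, C)", call. = FALSE)
  }
  for (i in seq_along(profiles)) check_profile(profiles[[i]], paste0("profiles[[", i, "]]"))
  invisible(profiles)
}
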