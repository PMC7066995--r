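#' Derive a reproducible sub-stream seed from a master seed
#'
#' Maps a master integer seed and a stage key (an arbitrary string such as
#' `"generate_true"` or `"grid/sim1/n100/rep3"`) to an integer seed, so that
#' every stage of a pipeline draws from its own reproducible stream instead
#' of consuming a shared global stream. The mapping is a fixed polynomial
#' hash over the key bytes modulo the Mersenne prime 2^31 - 1, mixed with the
#' master seed; it is stable across platforms and R versions.
#'
#' @param master Integer master seed.
#' @param stage_key Character scalar naming the stage (and any indices).
#' @return An integer in \[1, 2^31 - 2\], suitable for [set.seed()].
#' @examples
#' derive_seed(7, "generate_true")
#' derive_seed(7, "misclass") # a different stream
#' @export
derive_seed <- function(master, stage_key) {
  if (!is.numeric(master) || length(master) != 1L || is.na(master) ||
      master != round(master)) {
    stop("`master` must be a single integer", call. = FALSE)
  }
  if (!is.character(stage_key) || length(stage_key) != 1L || is.na(stage_key)) {
    stop("`stage_key` must be a single string", call. = FALSE)
  }
  p <- 2147483647 # 2^31 - 1
  h <- (abs(master) %% p)
  # fold in the sign so negative masters get their own streams
  if (master < 0) h <- mulmod(h + 11, 2654435761 %% p, p)
  for (byte in utf8ToInt(stage_key)) {
    h <- mulmod(h, 1000003, p)
    h <- (h + byte) %% p
  }
  h <- mulmod(h + nchar(stage_key), 69069, p)
  as.integer(h %% (p - 2) + 1)
}

# (a * b) mod m without exceeding double precision: split a into 16-bit halves
mulmod <- function(a, b, m) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% m) * (65536 %% m) + lo * b) %% m
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (or takes an equivalent named
#' list of inline overrides), validates it against the schema of the
#' requested subcommand, applies documented defaults and rejects unknown
#' keys. Every block is validated through its constructor before any
#' computation, so an out-of-range probability or a missing key fails here,
#' not mid-run.
#'
#' Schemas by subcommand (all accept `schema_version` (default 1), `seed`,
#' `out`):
#' \describe{
#'   \item{simulate}{`sim` (1-4) or explicit `beta0`, `beta1`, `beta2`; `n`;
#'     optional `prev_b`, `prev_c` (default 0.3, logged as an assumption);
#'     optional `profiles`.}
#'   \item{box1}{`p_a_given_b`, `p_a_given_not_b`, `prevalence_b`,
#'     `profile_a`, `profile_b` (each profile a list with `sensitivity`,
#'     `false_positive_rate`).}
#'   \item{fit}{`data` (cohort CSV path) or `counts` (named pattern counts);
#'     `mode` ("naive" or "adjusted"); optional `profiles`, `prior`, `mcmc`.}
#'   \item{grid}{`simulation_ids`, `sizes`, `replications`, optional
#'     `prev_b`, `prev_c`, `profiles`, `prior`, `mcmc`.}
#'   \item{multivar}{`data` (cohort CSV path), `preset`
#'     ("none"/"small"/"large"), optional `prior`, `mcmc`.}
#' }
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` when the
#'   whole configuration is supplied inline.
#' @param subcommand Which schema to validate against.
#' @param overrides Named list merged over the file contents (inline values
#'   win).
#' @return A validated `run_config` list with parsed blocks and defaults
#'   applied.
#' @export
load_and_validate <- function(path = NULL,
                              subcommand = c("simulate", "box1", "fit",
                                             "grid", "multivar"),
                              overrides = list()) {
  subcommand <- match.arg(subcommand)
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(raw)) raw <- list()
    # YAML 1.1 reads a bare key `n` as boolean FALSE; undo that for the
    # cohort-size key
    names(raw)[names(raw) == "FALSE"] <- "n"
  }
  raw[names(overrides)] <- overrides

  sv <- raw$schema_version %||% 1L
  if (!identical(as.integer(sv), 1L)) {
    stop("unsupported schema_version: ", sv, call. = FALSE)
  }

  schema <- config_schema(subcommand)
  unknown <- setdiff(names(raw), c(schema$required, names(schema$defaults),
                                   "schema_version", "seed", "out"))
  if (length(unknown) > 0) {
    stop("unknown configuration key", if (length(unknown) > 1) "s" else "",
         ": ", paste0("`", unknown, "`", collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(schema$required, names(raw))
  if (length(missing) > 0) {
    stop("missing required configuration key",
         if (length(missing) > 1) "s" else "", ": ",
         paste0("`", missing, "`", collapse = ", "), call. = FALSE)
  }
  defaults_used <- setdiff(names(schema$defaults), names(raw))
  for (k in defaults_used) raw[[k]] <- schema$defaults[[k]]

  cfg <- schema$parse(raw)
  cfg$subcommand <- subcommand
  cfg$schema_version <- 1L
  cfg$seed <- as.integer(raw$seed %||% 1L)
  cfg$out <- raw$out
  cfg$defaults_used <- defaults_used
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_profile_block <- function(x, name) {
  if (inherits(x, "misclass_profile")) return(x)
  if (is.character(x) && length(x) == 1L) return(error_preset(x))
  if (!is.list(x) || is.null(x$sensitivity) || is.null(x$false_positive_rate)) {
    stop("`", name, "` must be a list with `sensitivity` and ",
         "`false_positive_rate`", call. = FALSE)
  }
  extra <- setdiff(names(x), c("sensitivity", "false_positive_rate"))
  if (length(extra) > 0) {
    stop("unknown key `", extra[1], "` in `", name, "`", call. = FALSE)
  }
  tryCatch(misclass_profile(x$sensitivity, x$false_positive_rate),
           error = function(e) stop("invalid `", name, "`: ",
                                    conditionMessage(e), call. = FALSE))
}

parse_profiles_block <- function(x) {
  if (is.null(x)) return(default_profiles())
  if (!is.list(x) || length(x) != 3L) {
    stop("`profiles` must name three conditions (a, b, c)", call. = FALSE)
  }
  nm <- names(x) %||% c("a", "b", "c")
  out <- lapply(seq_along(x), function(i)
    parse_profile_block(x[[i]], paste0("profiles$", nm[i])))
  names(out) <- nm
  out
}

config_schema <- function(subcommand) {
  switch(
    subcommand,
    simulate = list(
      required = c("n"),
      defaults = list(sim = NULL, beta0 = NULL, beta1 = NULL, beta2 = NULL,
                      prev_b = 0.3, prev_c = 0.3, profiles = NULL),
      parse = function(raw) {
        params <- if (!is.null(raw$sim)) {
          if (any(!is.null(raw$beta0), !is.null(raw$beta1), !is.null(raw$beta2))) {
            stop("give either `sim` or explicit `beta0`/`beta1`/`beta2`, not both",
                 call. = FALSE)
          }
          simulation_params(raw$sim)
        } else if (!is.null(raw$beta0) && !is.null(raw$beta1) && !is.null(raw$beta2)) {
          logistic_params(raw$beta0, raw$beta1, raw$beta2)
        } else {
          stop("missing required configuration key: `sim` (or explicit betas)",
               call. = FALSE)
        }
        list(generator = generator_config(
          params = params, prev_b = raw$prev_b, prev_c = raw$prev_c,
          profiles = parse_profiles_block(raw$profiles),
          n = raw$n, seed = as.integer(raw$seed %||% 1L)))
      }
    ),
    box1 = list(
      required = c("p_a_given_b", "p_a_given_not_b", "prevalence_b",
                   "profile_a", "profile_b"),
      defaults = list(),
      parse = function(raw) {
        list(scenario = two_condition_scenario(
          raw$p_a_given_b, raw$p_a_given_not_b, raw$prevalence_b,
          parse_profile_block(raw$profile_a, "profile_a"),
          parse_profile_block(raw$profile_b, "profile_b")))
      }
    ),
    fit = list(
      required = character(),
      defaults = list(data = NULL, counts = NULL, mode = "adjusted",
                      profiles = NULL, prior = NULL, mcmc = NULL),
      parse = function(raw) {
        if (is.null(raw$data) && is.null(raw$counts)) {
          stop("missing required configuration key: `data` or `counts`",
               call. = FALSE)
        }
        if (!raw$mode %in% c("naive", "adjusted")) {
          stop("`mode` must be \"naive\" or \"adjusted\"", call. = FALSE)
        }
        profiles <- parse_profiles_block(raw$profiles)
        list(data = raw$data, counts = raw$counts, mode = raw$mode,
             profiles = profiles,
             prior = do.call(prior_spec,
                             c(list(misclass_values = profiles),
                               raw$prior %||% list())),
             mcmc = do.call(mcmc_config,
                            c(list(seed = as.integer(raw$seed %||% 1L)),
                              raw$mcmc %||% list())))
      }
    ),
    grid = list(
      required = c("simulation_ids", "sizes"),
      defaults = list(replications = 5L, prev_b = 0.3, prev_c = 0.3,
                      profiles = NULL, prior = NULL, mcmc = NULL),
      parse = function(raw) {
        profiles <- parse_profiles_block(raw$profiles)
        list(grid = grid_spec(
          simulation_ids = raw$simulation_ids, sizes = raw$sizes,
          replications = raw$replications,
          base_seed = as.integer(raw$seed %||% 1L),
          prev_b = raw$prev_b, prev_c = raw$prev_c, profiles = profiles,
          prior = do.call(prior_spec,
                          c(list(misclass_values = profiles),
                            raw$prior %||% list())),
          mcmc = do.call(mcmc_config,
                         c(list(seed = as.integer(raw$seed %||% 1L)),
                           raw$mcmc %||% list()))))
      }
    ),
    multivar = list(
      required = c("data"),
      defaults = list(preset = "none", prior = NULL, mcmc = NULL),
      parse = function(raw) {
        list(data = raw$data, preset = error_preset(raw$preset),
             prior_args = raw$prior %||% list(),
             mcmc = do.call(mcmc_config,
                            c(list(seed = as.integer(raw$seed %||% 1L)),
                              raw$mcmc %||% list())))
      }
    )
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$subcommand, "(schema_version", paste0(x$schema_version, ")\n"))
  if (length(x$defaults_used) > 0) {
    cat("  defaults applied:", paste(x$defaults_used, collapse = ", "), "\n")
  }
  invisible(x)
}

# plain-text log line with ISO-8601 timestamp, to stderr
log_line <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
}
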