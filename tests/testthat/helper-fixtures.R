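# Shared fixtures: the worked two-condition scenario and small cohorts.

box1_scenario <- function() {
  two_condition_scenario(
    p_a_given_b = 0.6, p_a_given_not_b = 0.2, prevalence_b = 0.1,
    profile_a = misclass_profile(0.6, 0.05),
    profile_b = misclass_profile(0.85, 0.03)
  )
}

# brute-force pattern probabilities by exhaustive enumeration over the
# 8 latent x 8 observed states, coded independently of the package's
# matrix formulation
enumerate_pattern_probs <- function(beta, prev_b, prev_c, profiles) {
  labs <- vapply(0:7, function(i) paste0(i %/% 4, (i %/% 2) %% 2, i %% 2), "")
  probs <- setNames(numeric(8), labs)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    p_a <- plogis(beta[1] + beta[2] * b + beta[3] * cc)
    p_latent <- (if (a == 1) p_a else 1 - p_a) *
      (if (b == 1) prev_b else 1 - prev_b) *
      (if (cc == 1) prev_c else 1 - prev_c)
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      em <- 1
      tr <- c(a, b, cc)
      ob <- c(da, db, dc)
      for (j in 1:3) {
        s <- profiles[[j]]$sensitivity
        g <- profiles[[j]]$false_positive_rate
        pd <- if (tr[j] == 1) s else g
        em <- em * (if (ob[j] == 1) pd else 1 - pd)
      }
      key <- paste0(da, db, dc)
      probs[key] <- probs[key] + p_latent * em
    }
  }
  probs[sort(names(probs))]
}

# Monte-Carlo simulation of the two-condition hierarchy (B -> A -> records)
simulate_box1_draws <- function(scenario, n, seed) {
  set.seed(seed)
  b <- rbinom(n, 1, scenario$prevalence_b)
  a <- rbinom(n, 1, ifelse(b == 1, scenario$p_a_given_b,
                           scenario$p_a_given_not_b))
  da <- rbinom(n, 1, ifelse(a == 1, scenario$profile_a$sensitivity,
                            scenario$profile_a$false_positive_rate))
  db <- rbinom(n, 1, ifelse(b == 1, scenario$profile_b$sensitivity,
                            scenario$profile_b$false_positive_rate))
  data.frame(a = a, b = b, da = da, db = db)
}

# small deterministic cohort with hand-countable patterns
handmade_cohort <- function() {
  rec <- rbind(c(0, 0, 0),
               c(0, 0, 0),
               c(1, 0, 1),
               c(1, 1, 1),
               c(0, 1, 0),
               c(1, 0, 1))
  new_cohort(recorded = rec, condition_names = c("a", "b", "c"))
}

quiet_profile <- function(s, g) suppressWarnings(misclass_profile(s, g))

# small but informative pattern-count fixture for sampler tests
toy_counts <- function(n = 30, seed = 404) {
  cfg <- generator_config(simulation_params(4), prev_b = 0.3, prev_c = 0.3,
                          n = n, seed = seed)
  tabulate_patterns(generate_cohort(cfg))
}
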