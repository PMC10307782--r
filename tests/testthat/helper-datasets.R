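# Shared fixture builders (everything is generated in code).

# A design-like data frame repeating one trial `n` times; accepted by
# simulate_choices() and the likelihood functions.
repeated_trial <- function(n, condition = "costly", sd = 10,
                           x1 = 90, x2 = 10, x3 = 50) {
  d <- data.frame(session = 1L, block = 1L, trial = seq_len(n),
                  condition = condition, sd = sd, x1 = x1, x2 = x2,
                  x3 = x3, is_filler = FALSE)
  attr(d, "options") <- tpp_options()
  attr(d, "multiplier") <- 3
  d
}

# One simulated subject on the full study design.
quick_dataset <- function(model = "hyperbolic_punishment",
                          params = c(gamma = 0.6, k = 0.1, beta = 0.5),
                          design_seed = 101, choice_seed = 202,
                          miss_rate = 0) {
  des <- build_design(study_design(), seed = design_seed)
  simulate_choices(des, model, params, seed = choice_seed,
                   miss_rate = miss_rate)
}

# Exhaustive per-option oracle: evaluates the transform and the TPIA
# utility option by option with the scalar user-facing functions, never
# via the vectorized internal path.
oracle_option_utilities <- function(trial, params, model,
                                    options = tpp_options(),
                                    multiplier = 3) {
  spec <- model_spec(model)
  vapply(options, function(p) {
    if (spec$level == "punishment") {
      p_subj <- if (spec$family == "hyperbolic") {
        hyperbolic_punishment(p, trial$sd, params[["k"]])
      } else {
        power_punishment(p, trial$sd, params[["k"]], params[["w"]])
      }
      g <- params[["gamma"]]
      own <- if (trial$condition == "costly") max(trial$x3 - p_subj, 0) else trial$x3
      own - g * abs(max(trial$x1 - multiplier * p_subj, 0) - trial$x2)
    } else {
      g <- if (spec$family == "hyperbolic") {
        hyperbolic_inequity(params[["gamma"]], trial$sd, params[["k"]])
      } else {
        power_inequity(params[["gamma"]], trial$sd, params[["k"]],
                       params[["w"]])
      }
      own <- if (trial$condition == "costly") max(trial$x3 - p, 0) else trial$x3
      own - g * abs(max(trial$x1 - multiplier * p, 0) - trial$x2)
    }
  }, numeric(1))
}
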