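# Core utility model and social-distance transforms.

#' Third-party inequity-aversion (TPIA) utility
#'
#' Utility of a third-party observer who may spend part of an endowment
#' `x3` to punish a dictator. A punishment of `p` costs the observer `p`
#' (in the costly condition) and reduces the dictator's payoff by
#' `multiplier * p`; neither the observer's payoff nor the dictator's
#' post-punishment payoff can fall below zero. The observer dislikes the
#' absolute payoff difference between dictator and recipient with weight
#' `gamma`:
#'
#' \deqn{U = \max(x_3 - p, 0) - \gamma \, | \max(x_1 - m p, 0) - x_2 |}
#'
#' In the free (control) condition punishment costs nothing, so the own
#' payoff term is `x3` without deduction while the dictator-reduction term
#' is unchanged.
#'
#' @param x1 dictator's pre-punishment payoff (money units).
#' @param x2 recipient's payoff (money units).
#' @param x3 observer's endowment (money units, 50 in the study design).
#' @param p punishment amount spent by the observer, `>= 0`. Vectorized.
#' @param gamma inequity-aversion weight in `[0, 1]`.
#' @param multiplier factor by which punishment reduces the dictator's
#'   payoff (3 in the study design).
#' @param costly logical; `TRUE` for the costly condition, `FALSE` for the
#'   free/control condition.
#' @return numeric vector of utilities, same length as `p`.
#' @examples
#' tpia_utility(90, 10, 50, p = c(0, 15, 30), gamma = 0.5)
#' @export
tpia_utility <- function(x1, x2, x3, p, gamma, multiplier = 3, costly = TRUE) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("`p` must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  own <- if (costly) pmax(x3 - p, 0) else rep(x3, length.out = length(p))
  own - gamma * abs(pmax(x1 - multiplier * p, 0) - x2)
}

#' Dictator payoff after punishment
#'
#' The dictator's post-punishment payoff `max(x1 - multiplier * p, 0)`,
#' exposed because the clamped payoff grid (e.g. 90, 75, ..., 0 for the
#' 90 vs 10 allocation with options 0..30 and multiplier 3) is a basic
#' design invariant of the task.
#'
#' @inheritParams tpia_utility
#' @return numeric vector of post-punishment dictator payoffs.
#' @export
dictator_payoff <- function(x1, p, multiplier = 3) {
  if (any(p < 0)) stop("`p` must be non-negative", call. = FALSE)
  pmax(x1 - multiplier * p, 0)
}

.check_sd_k <- function(sd, k, require_positive_k = TRUE) {
  if (any(!is.finite(sd)) || any(sd < 1)) {
    stop("social distance `sd` must be >= 1", call. = FALSE)
  }
  if (require_positive_k && (!is.finite(k) || k <= 0)) {
    stop("discount rate `k` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Hyperbolic social-distance transform of the punishment level
#'
#' Maps a chosen (nominal) punishment level to its subjective level,
#' inflated at small social distances: `(1 + 1/(k * sd)) * p_sd`. For fixed
#' `p_sd > 0` the subjective level strictly decreases with `sd` and tends
#' to `p_sd` as `sd` grows.
#'
#' @param p_sd nominal punishment level (money units). Vectorized.
#' @param sd social distance, `>= 1`. Vectorized.
#' @param k positive discount rate.
#' @return subjective punishment level(s).
#' @export
hyperbolic_punishment <- function(p_sd, sd, k) {
  .check_sd_k(sd, k)
  (1 + 1 / (k * sd)) * p_sd
}

#' Hyperbolic social-distance transform of the inequity-aversion weight
#'
#' Applies the hyperbolic discounting factor to an unbounded baseline
#' weight and squashes the result through the logistic sigmoid so the
#' effective weight lies in (0, 1):
#' `gamma = sigmoid((1 + 1/(k * sd)) * gamma_sd)`.
#'
#' @param gamma_sd unbounded baseline inequity-aversion parameter.
#' @param sd social distance, `>= 1`. Vectorized.
#' @param k positive discount rate.
#' @return effective inequity-aversion weight(s) in (0, 1).
#' @export
hyperbolic_inequity <- function(gamma_sd, sd, k) {
  .check_sd_k(sd, k)
  stats::plogis((1 + 1 / (k * sd)) * gamma_sd)
}

#' Power-function social-distance inflation of the punishment level
#'
#' Adds an inflation term that grows with social distance:
#' `p_sd + k * sd^w`.
#'
#' @inheritParams hyperbolic_punishment
#' @param k curvature of the power function (any real; `k = 0` is the
#'   identity).
#' @param w power exponent (any real).
#' @return subjective punishment level(s).
#' @export
power_punishment <- function(p_sd, sd, k, w) {
  .check_sd_k(sd, k, require_positive_k = FALSE)
  p_sd + k * sd^w
}

#' Power-function social-distance inflation of the inequity-aversion weight
#'
#' `gamma = sigmoid(gamma_sd + k * sd^w)`.
#'
#' @inheritParams hyperbolic_inequity
#' @param k curvature of the power function (any real).
#' @param w power exponent (any real).
#' @return effective inequity-aversion weight(s) in (0, 1).
#' @export
power_inequity <- function(gamma_sd, sd, k, w) {
  .check_sd_k(sd, k, require_positive_k = FALSE)
  stats::plogis(gamma_sd + k * sd^w)
}

#' Model specifications
#'
#' The four candidate social-distance models. Each applies one transform
#' before the TPIA utility:
#' \describe{
#'   \item{`hyperbolic_punishment`}{hyperbolic discounting of the
#'     punishment level; parameters `gamma` (in `[0,1]`), `k > 0`,
#'     `beta > 0`.}
#'   \item{`hyperbolic_inequity`}{hyperbolic discounting of the
#'     inequity-aversion weight; parameters `gamma` (unbounded baseline,
#'     squashed by the sigmoid), `k > 0`, `beta > 0`.}
#'   \item{`power_punishment`}{power-function inflation of the punishment
#'     level; adds exponent `w`.}
#'   \item{`power_inequity`}{power-function inflation of the
#'     inequity-aversion weight; adds exponent `w`.}
#' }
#' `beta` is the inverse temperature of the softmax choice rule shared by
#' all models. For `*_punishment` models `gamma` is the inequity weight
#' itself; for `*_inequity` models it is the pre-sigmoid baseline and may
#' take any value. During fitting, `gamma` of the punishment models is
#' logit-transformed, `k` and `beta` are log-transformed, and `w` (power
#' models) and `gamma` of the inequity models are unconstrained.
#'
#' @param name one of `"hyperbolic_punishment"`, `"hyperbolic_inequity"`,
#'   `"power_punishment"`, `"power_inequity"`.
#' @return an object of class `model_spec`: a list with the model `name`,
#'   its `level` ("punishment" or "inequity"), `family` ("hyperbolic" or
#'   "power"), parameter names, number of parameters, and per-parameter
#'   transform labels.
#' @export
model_spec <- function(name = tpp_models()) {
  name <- match.arg(name)
  level <- if (grepl("punishment$", name)) "punishment" else "inequity"
  family <- if (grepl("^hyperbolic", name)) "hyperbolic" else "power"
  params <- c("gamma", "k", if (family == "power") "w", "beta")
  transform <- c(
    gamma = if (level == "punishment") "logit" else "identity",
    k = "log",
    if (family == "power") c(w = "identity"),
    beta = "log"
  )
  structure(
    list(name = name, level = level, family = family,
         params = params, n_params = length(params),
         transform = transform[params]),
    class = "model_spec"
  )
}

#' Names of the four candidate models
#' @return character vector of model names.
#' @export
tpp_models <- function() {
  c("hyperbolic_punishment", "hyperbolic_inequity",
    "power_punishment", "power_inequity")
}

.as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

.check_params <- function(params, spec) {
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop(sprintf("model '%s' needs parameter(s): %s", spec$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (spec$level == "punishment" &&
      (params[["gamma"]] < 0 || params[["gamma"]] > 1)) {
    stop("`gamma` must lie in [0, 1] for punishment-transform models",
         call. = FALSE)
  }
  if (params[["k"]] <= 0 && spec$family == "hyperbolic") {
    stop("`k` must be positive", call. = FALSE)
  }
  if ("beta" %in% names(params) && params[["beta"]] <= 0) {
    stop("`beta` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

# Option-by-trial utility matrix (n_trials x n_options), vectorized over
# trials. `trials` needs columns condition, sd, x1, x2, x3.
.utility_matrix <- function(trials, params, spec, options, multiplier = 3) {
  n <- nrow(trials)
  m <- length(options)
  P <- matrix(options, n, m, byrow = TRUE)
  sdist <- trials$sd
  if (spec$level == "punishment") {
    g <- params[["gamma"]]
    P_subj <- if (spec$family == "hyperbolic") {
      (1 + 1 / (params[["k"]] * sdist)) * P
    } else {
      P + params[["k"]] * sdist^params[["w"]]
    }
  } else {
    g <- if (spec$family == "hyperbolic") {
      stats::plogis((1 + 1 / (params[["k"]] * sdist)) * params[["gamma"]])
    } else {
      stats::plogis(params[["gamma"]] + params[["k"]] * sdist^params[["w"]])
    }
    P_subj <- P
  }
  dict <- pmax(trials$x1 - multiplier * P_subj, 0)
  own <- pmax(trials$x3 - P_subj, 0)
  free <- trials$condition != "costly"
  if (any(free)) own[free, ] <- trials$x3[free]
  own - g * abs(dict - trials$x2)
}

#' Option-wise utilities for one trial
#'
#' Applies the model's social-distance transform (to the punishment level
#' or to the inequity-aversion weight) and then the TPIA utility to every
#' punishment option of a trial. For punishment-level models the subjective
#' punishment replaces the nominal one in both the observer-cost term and
#' the dictator-reduction term.
#'
#' @param trial a list or one-row data frame with fields `condition`
#'   (`"costly"` or `"free"`), `sd`, `x1`, `x2`, `x3`, and optionally
#'   `options` and `multiplier`.
#' @param params named numeric vector of model parameters (see
#'   [model_spec()]).
#' @param model a `model_spec` or model name.
#' @param options punishment option set; defaults to the trial's own, else
#'   the study grid 0, 5, ..., 30.
#' @param multiplier punishment multiplier; defaults to the trial's own,
#'   else 3.
#' @return numeric vector of utilities, one per option.
#' @export
option_utilities <- function(trial, params, model,
                             options = NULL, multiplier = NULL) {
  spec <- .as_model_spec(model)
  .check_params(params, spec)
  if (is.null(options)) {
    options <- if (!is.null(trial$options)) unlist(trial$options) else tpp_options()
  }
  if (is.null(multiplier)) {
    multiplier <- if (!is.null(trial$multiplier)) trial$multiplier else 3
  }
  if (is.unsorted(options, strictly = TRUE) || options[1] != 0) {
    stop("`options` must be strictly increasing and start at 0", call. = FALSE)
  }
  tr <- data.frame(condition = trial$condition, sd = trial$sd,
                   x1 = trial$x1, x2 = trial$x2, x3 = trial$x3)
  drop(.utility_matrix(tr, params, spec, options, multiplier))
}

#' Punishment option grid of the study design
#' @return the seven punishment amounts 0, 5, 10, 15, 20, 25, 30.
#' @export
tpp_options <- function() seq(0, 30, by = 5)

#' Softmax choice probabilities
#'
#' Probability of choosing each option under a softmax rule with inverse
#' temperature `beta`: `P_j = exp(beta * U_j) / sum_l exp(beta * U_l)`.
#' Computed with a log-sum-exp shift, so it is invariant to adding a
#' constant to all utilities and stable for large `beta`.
#'
#' @param utilities numeric vector of option utilities, or a matrix with
#'   one row per trial.
#' @param beta positive inverse temperature.
#' @return probability vector (or matrix) matching `utilities`.
#' @export
choice_probabilities <- function(utilities, beta) {
  if (!is.finite(beta) || beta <= 0) {
    stop("`beta` must be positive", call. = FALSE)
  }
  if (any(!is.finite(utilities))) {
    stop("utilities must be finite", call. = FALSE)
  }
  if (is.matrix(utilities)) {
    z <- beta * utilities
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- beta * utilities
    e <- exp(z - max(z))
    e / sum(e)
  }
}
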