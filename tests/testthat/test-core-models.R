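# The TPIA utility, the four social-distance transforms, option-wise
# utilities and the softmax choice rule.

test_that("TPIA utility evaluates worked cases and clamps payoffs", {
  expect_equal(tpia_utility(90, 10, 50, p = 0, gamma = 0), 50)
  expect_equal(tpia_utility(90, 10, 50, p = 30, gamma = 1), 10)
  expect_equal(tpia_utility(90, 10, 50, p = 15, gamma = 0.5), 17.5)
  # free condition: no deduction of the observer's endowment
  expect_equal(tpia_utility(90, 10, 50, p = 30, gamma = 0, costly = FALSE), 50)
  expect_equal(tpia_utility(90, 10, 50, p = 30, gamma = 1, costly = FALSE),
               50 - abs(0 - 10))
  # post-punishment dictator payoffs for the 90 vs 10 allocation
  expect_equal(dictator_payoff(90, tpp_options()),
               c(90, 75, 60, 45, 30, 15, 0))
  expect_equal(dictator_payoff(90, 15), 45)
  expect_equal(90 - dictator_payoff(90, 10), 30)
})

test_that("TPIA utility rejects out-of-domain arguments", {
  expect_error(tpia_utility(90, 10, 50, p = -1, gamma = 0.5), "non-negative")
  expect_error(tpia_utility(90, 10, 50, p = 5, gamma = 1.2), "\\[0, 1\\]")
  expect_error(tpia_utility(90, 10, 50, p = 5, gamma = -0.1), "\\[0, 1\\]")
})

test_that("social-distance transforms match hand-computed values", {
  expect_equal(hyperbolic_punishment(10, sd = 1, k = 1), 20)
  expect_equal(hyperbolic_punishment(0, sd = 5, k = 0.3), 0)
  expect_equal(hyperbolic_punishment(10, sd = 100, k = 1), 10.1)
  expect_equal(hyperbolic_inequity(0, sd = 3, k = 0.2), 0.5)
  expect_equal(hyperbolic_inequity(1, sd = 1, k = 1), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(hyperbolic_inequity(50, sd = 1, k = 1), 1, tolerance = 1e-6)
  expect_equal(power_punishment(10, sd = 1, k = 2, w = 3), 12)
  expect_equal(power_punishment(10, sd = 4, k = 0, w = 1), 10)
  expect_equal(power_punishment(5, sd = 10, k = 0.5, w = 2), 55)
  expect_equal(power_inequity(0, sd = 1, k = 0, w = 1), 0.5)
  expect_equal(power_inequity(-3, sd = 1, k = 3, w = 1), 0.5)
  expect_equal(power_inequity(0, sd = 2, k = 1, w = 1), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
})

test_that("transforms reject non-positive social distance and bad k", {
  expect_error(hyperbolic_punishment(10, sd = 0, k = 1), ">= 1")
  expect_error(hyperbolic_punishment(10, sd = 2, k = 0), "positive")
  expect_error(hyperbolic_punishment(10, sd = 2, k = -1), "positive")
  expect_error(hyperbolic_inequity(1, sd = -1, k = 1), ">= 1")
  expect_error(hyperbolic_inequity(1, sd = 2, k = 0), "positive")
  expect_error(power_punishment(10, sd = 0, k = 1, w = 1), ">= 1")
  expect_error(power_inequity(0, sd = 0.5, k = 1, w = 1), ">= 1")
})

test_that("hyperbolic punishment discounting is decreasing in sd with limit p_sd", {
  set.seed(42)
  sd_grid <- c(1, 2, 3, 5, 10, 20, 50, 100)
  for (i in 1:20) {
    p <- runif(1, 1, 30)
    k <- runif(1, 0.01, 2)
    vals <- hyperbolic_punishment(p, sd_grid, k)
    expect_true(all(diff(vals) < 0))
    expect_true(all(vals > p))
    expect_equal(hyperbolic_punishment(p, 1e9, k), p, tolerance = 1e-6)
  }
})

test_that("option utilities apply transform then utility, matching the oracle", {
  trials <- list(
    list(condition = "costly", sd = 100, x1 = 90, x2 = 10, x3 = 50),
    list(condition = "costly", sd = 1, x1 = 85, x2 = 15, x3 = 50),
    list(condition = "free", sd = 5, x1 = 80, x2 = 20, x3 = 50)
  )
  cases <- list(
    list(model = "hyperbolic_punishment", params = c(gamma = 0.5, k = 0.1, beta = 1)),
    list(model = "hyperbolic_inequity", params = c(gamma = 0.8, k = 0.2, beta = 1)),
    list(model = "power_punishment", params = c(gamma = 0.7, k = 0.3, w = 0.8, beta = 1)),
    list(model = "power_inequity", params = c(gamma = -0.5, k = 0.4, w = 0.6, beta = 1))
  )
  for (tr in trials) {
    for (cs in cases) {
      got <- option_utilities(tr, cs$params, cs$model)
      want <- oracle_option_utilities(tr, cs$params, cs$model)
      expect_equal(got, want, tolerance = 1e-12,
                   info = paste(cs$model, tr$condition, tr$sd))
      expect_length(got, 7)
    }
  }
  # argmax of the 7-option evaluation for the quoted worked case
  tr <- trials[[1]]
  pars <- c(gamma = 0.5, k = 0.1, beta = 1)
  u <- option_utilities(tr, pars, "hyperbolic_punishment")
  expect_equal(which.max(u),
               which.max(oracle_option_utilities(tr, pars,
                                                 "hyperbolic_punishment")))
})

test_that("with gamma = 0 utility is cost-only: decreasing when costly, flat when free", {
  tr <- list(condition = "costly", sd = 10, x1 = 90, x2 = 10, x3 = 50)
  # identity transform settings (power model with k = 0): strictly 50 - p
  u_id <- option_utilities(tr, c(gamma = 0, k = 0, w = 1, beta = 1),
                           "power_punishment")
  expect_true(all(diff(u_id) < 0))
  expect_equal(u_id, 50 - tpp_options())
  # with an active transform the cost is inflated (and clamped at 0), but
  # not punishing stays the unique maximizer
  u_hyp <- option_utilities(tr, c(gamma = 0, k = 0.1, beta = 1),
                            "hyperbolic_punishment")
  expect_equal(which.max(u_hyp), 1L)
  expect_true(all(u_hyp[-1] < u_hyp[1]))
  tr$condition <- "free"
  u_free <- option_utilities(tr, c(gamma = 0, k = 0.1, beta = 1),
                             "hyperbolic_punishment")
  expect_equal(u_free, rep(50, 7))
})

test_that("hyperbolic punishment model degenerates to plain TPIA as k grows", {
  tr <- list(condition = "costly", sd = 2, x1 = 85, x2 = 15, x3 = 50)
  u_big_k <- option_utilities(tr, c(gamma = 0.4, k = 1e9, beta = 1),
                              "hyperbolic_punishment")
  u_plain <- tpia_utility(85, 15, 50, tpp_options(), gamma = 0.4)
  expect_equal(u_big_k, u_plain, tolerance = 1e-6)
})

test_that("softmax probabilities normalize, respect limits and shift invariance", {
  expect_equal(choice_probabilities(rep(3, 7), beta = 2), rep(1 / 7, 7))
  expect_equal(choice_probabilities(c(0, 1), beta = 1),
               c(1, exp(1)) / (1 + exp(1)), tolerance = 1e-12)
  u <- c(1, 5, 2, 0, 3, 4, 2.5)
  p_big <- choice_probabilities(u, beta = 500)
  expect_equal(which.max(p_big), which.max(u))
  expect_gt(p_big[which.max(u)], 0.999)
  set.seed(7)
  for (i in 1:50) {
    v <- rnorm(7, sd = runif(1, 0.1, 20))
    b <- runif(1, 0.01, 10)
    p <- choice_probabilities(v, b)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(choice_probabilities(v + rnorm(1, sd = 50), b), p,
                 tolerance = 1e-9)
  }
  expect_error(choice_probabilities(c(1, NA), 1), "finite")
  expect_error(choice_probabilities(c(1, 2), 0), "positive")
})

test_that("model specs expose the right parameter sets and transforms", {
  expect_setequal(tpp_models(),
                  c("hyperbolic_punishment", "hyperbolic_inequity",
                    "power_punishment", "power_inequity"))
  hp <- model_spec("hyperbolic_punishment")
  expect_equal(hp$params, c("gamma", "k", "beta"))
  expect_equal(hp$n_params, 3)
  expect_equal(unname(hp$transform["gamma"]), "logit")
  pi_ <- model_spec("power_inequity")
  expect_equal(pi_$params, c("gamma", "k", "w", "beta"))
  expect_equal(unname(pi_$transform["gamma"]), "identity")
  expect_error(option_utilities(list(condition = "costly", sd = 1, x1 = 90,
                                     x2 = 10, x3 = 50),
                                c(gamma = 1.5, k = 0.1, beta = 1),
                                "hyperbolic_punishment"),
               "\\[0, 1\\]")
})
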