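# Study-faithful design generation and forward simulation.

#' Study design specification
#'
#' Defaults reproduce the scanned task: 6 sessions of 54 trials; per
#' session 48 unfair target trials spread over 12 blocks of 4 (half the
#' blocks costly, half free), covering all 24 combinations of 8 social
#' distances and 3 unfair allocations once per condition; plus 6 quasi-fair
#' filler trials per session.
#'
#' @param n_sessions number of sessions.
#' @param blocks_per_session number of blocks per session (half per
#'   condition).
#' @param sd_levels social distances used for target trials.
#' @param allocations two-column matrix (x1, x2) of unfair target
#'   allocations.
#' @param filler_allocations two-column matrix of quasi-fair filler
#'   allocations; each is used `fillers_per_session / nrow` times per
#'   session.
#' @param fillers_per_session filler trials per session.
#' @param endowment observer endowment per trial.
#' @param options punishment option grid.
#' @param multiplier punishment multiplier.
#' @param filler_assignment `"balanced"` places half the fillers in costly
#'   and half in free blocks (one per filler allocation and condition);
#'   `"any"` scatters them over blocks regardless of condition.
#' @return object of class `study_design` (a list of the above settings).
#' @export
study_design <- function(n_sessions = 6,
                         blocks_per_session = 12,
                         sd_levels = c(1, 2, 3, 5, 10, 20, 50, 100),
                         allocations = cbind(x1 = c(90, 85, 80),
                                             x2 = c(10, 15, 20)),
                         filler_allocations = cbind(x1 = c(65, 60, 55),
                                                    x2 = c(35, 40, 45)),
                         fillers_per_session = 6,
                         endowment = 50,
                         options = tpp_options(),
                         multiplier = 3,
                         filler_assignment = c("balanced", "any")) {
  filler_assignment <- match.arg(filler_assignment)
  spec <- list(n_sessions = n_sessions,
               blocks_per_session = blocks_per_session,
               sd_levels = sd_levels,
               allocations = allocations,
               filler_allocations = filler_allocations,
               fillers_per_session = fillers_per_session,
               endowment = endowment,
               options = options,
               multiplier = multiplier,
               conditions = c("costly", "free"),
               filler_assignment = filler_assignment)
  n_combo <- length(sd_levels) * nrow(allocations)
  blocks_per_cond <- blocks_per_session / 2
  if (blocks_per_session %% 2 != 0 || n_combo %% blocks_per_cond != 0) {
    stop("design inconsistent: sd x allocation combinations must divide ",
         "evenly into the blocks of each condition", call. = FALSE)
  }
  if (filler_assignment == "balanced" &&
      fillers_per_session %% (2 * nrow(filler_allocations)) != 0) {
    stop("design inconsistent: balanced fillers need a multiple of ",
         2 * nrow(filler_allocations), " fillers per session", call. = FALSE)
  }
  structure(spec, class = "study_design")
}

# Independent sub-streams from one master seed (design shuffling vs choice
# sampling vs per-subject streams all get their own derived seed).
.derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(.Machine$integer.max - 1L, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Build a pseudo-randomized trial list
#'
#' Generates the full ordered trial list of one scanning protocol. Per
#' session the 24 sd-by-allocation target combinations appear once per
#' condition, partitioned at random into the condition's blocks (4 targets
#' per block), block order and within-block trial order are shuffled, and
#' filler trials are inserted according to the design's filler policy.
#' Fillers get a social distance drawn from the design's levels.
#'
#' @param spec a [study_design()].
#' @param seed integer seed; identical seeds give identical designs.
#' @return a data frame of class `trial_design` with columns `session`,
#'   `block`, `trial` (index within session), `condition`, `sd`, `x1`,
#'   `x2`, `x3`, `is_filler`; the option grid and multiplier are kept as
#'   attributes `options` and `multiplier`.
#' @export
build_design <- function(spec = study_design(), seed = NULL) {
  stopifnot(inherits(spec, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  conditions <- spec$conditions
  blocks_per_cond <- spec$blocks_per_session / 2
  combos <- expand.grid(sd = spec$sd_levels,
                        alloc = seq_len(nrow(spec$allocations)))
  n_combo <- nrow(combos)
  targets_per_block <- n_combo / blocks_per_cond

  sessions <- lapply(seq_len(spec$n_sessions), function(s) {
    block_cond <- sample(rep(conditions, each = blocks_per_cond))
    rows <- list()
    for (cond in conditions) {
      cond_blocks <- which(block_cond == cond)
      ord <- sample.int(n_combo)
      block_of <- rep(cond_blocks, each = targets_per_block)
      rows[[cond]] <- data.frame(
        session = s,
        block = block_of,
        condition = cond,
        sd = combos$sd[ord],
        x1 = spec$allocations[combos$alloc[ord], "x1"],
        x2 = spec$allocations[combos$alloc[ord], "x2"],
        is_filler = FALSE
      )
    }
    n_fill <- spec$fillers_per_session
    alloc_idx <- rep(seq_len(nrow(spec$filler_allocations)),
                     length.out = n_fill)
    if (spec$filler_assignment == "balanced") {
      fill_block <- c(sample(which(block_cond == conditions[1]), n_fill / 2),
                      sample(which(block_cond == conditions[2]), n_fill / 2))
    } else {
      fill_block <- sample.int(spec$blocks_per_session, n_fill,
                               replace = n_fill > spec$blocks_per_session)
    }
    fillers <- data.frame(
      session = s,
      block = fill_block,
      condition = block_cond[fill_block],
      sd = sample(spec$sd_levels, n_fill, replace = TRUE),
      x1 = spec$filler_allocations[alloc_idx, "x1"],
      x2 = spec$filler_allocations[alloc_idx, "x2"],
      is_filler = TRUE
    )
    ses <- rbind(rows[[1]], rows[[2]], fillers)
    # shuffle within block, keep blocks in order
    ses <- ses[order(ses$block, sample.int(nrow(ses))), ]
    ses$trial <- seq_len(nrow(ses))
    ses
  })
  out <- do.call(rbind, sessions)
  out$x3 <- spec$endowment
  out <- out[, c("session", "block", "trial", "condition", "sd",
                 "x1", "x2", "x3", "is_filler")]
  rownames(out) <- NULL
  attr(out, "options") <- spec$options
  attr(out, "multiplier") <- spec$multiplier
  class(out) <- c("trial_design", "data.frame")
  out
}

#' Simulate choices from a model
#'
#' Forward-simulates one subject: for every trial (fillers included,
#' flagged by `is_filler`) option utilities are computed under the given
#' model and parameters, and a choice is sampled from the softmax
#' probabilities. A miss rate can blank out a random subset of responses.
#'
#' @param design a trial list from [build_design()].
#' @param model a `model_spec` or model name.
#' @param params named parameter vector including `beta`.
#' @param seed integer seed for the choice sampling.
#' @param subject_id subject label.
#' @param miss_rate probability that a trial has no response (choice `NA`).
#' @return a `choice_dataset`: the design data frame plus `subject`,
#'   `option_chosen` (1-based option index, `NA` for misses) and
#'   `punishment` (chosen amount), with generator metadata in attributes
#'   `generator_model`, `generator_params`, `seed`.
#' @export
simulate_choices <- function(design, model, params, seed = NULL,
                             subject_id = "s01", miss_rate = 0) {
  spec <- .as_model_spec(model)
  .check_params(params, spec)
  if (!is.null(seed)) set.seed(seed)
  options <- attr(design, "options") %||% tpp_options()
  multiplier <- attr(design, "multiplier") %||% 3
  U <- .utility_matrix(design, params, spec, options, multiplier)
  P <- choice_probabilities(U, params[["beta"]])
  n <- nrow(design)
  # inverse-CDF sampling, vectorized over trials
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n)
  choice <- rowSums(u > cum) + 1L
  if (miss_rate > 0) choice[stats::runif(n) < miss_rate] <- NA_integer_
  out <- design
  out$subject <- subject_id
  out$option_chosen <- choice
  out$punishment <- options[choice]
  out <- out[, c("subject", "session", "block", "trial", "condition", "sd",
                 "x1", "x2", "x3", "is_filler", "option_chosen", "punishment")]
  attr(out, "options") <- options
  attr(out, "multiplier") <- multiplier
  attr(out, "generator_model") <- spec$name
  attr(out, "generator_params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("choice_dataset", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default population parameter distributions
#'
#' Uniform sampling ranges used by [sample_population()] for recovery
#' studies: `gamma ~ U(0.2, 0.8)` for punishment-level models (the weight
#' itself) or `U(-1, 2)` for inequity-level models (pre-sigmoid baseline),
#' `k ~ U(0.02, 0.5)`, `w ~ U(0.2, 1)` (power models), and
#' `beta ~ U(0.2, 1)`.
#'
#' @param model a `model_spec` or model name.
#' @return named list of `c(lower, upper)` ranges.
#' @export
default_param_priors <- function(model) {
  spec <- .as_model_spec(model)
  pr <- list(
    gamma = if (spec$level == "punishment") c(0.2, 0.8) else c(-1, 2),
    k = c(0.02, 0.5),
    w = c(0.2, 1),
    beta = c(0.2, 1)
  )
  pr[spec$params]
}

#' Simulate a population of subjects
#'
#' Draws per-subject parameters from the given distributions, builds one
#' pseudo-randomized design per subject, and simulates choices. True
#' parameters are stored for recovery scoring.
#'
#' @param n_subjects number of subjects.
#' @param model generating `model_spec` or name.
#' @param param_priors named list; each element is either a numeric
#'   `c(lower, upper)` (uniform) or a function `function(n)` returning `n`
#'   draws. Out-of-bounds draws are resampled up to 100 times.
#' @param design_spec a [study_design()].
#' @param seed master seed; independent sub-streams are derived for each
#'   subject's design and choices.
#' @param miss_rate per-trial no-response probability.
#' @return list of `choice_dataset`s with attribute `true_params` (a data
#'   frame of the generating parameters, one row per subject).
#' @export
sample_population <- function(n_subjects, model,
                              param_priors = default_param_priors(model),
                              design_spec = study_design(),
                              seed = NULL, miss_rate = 0) {
  stopifnot(n_subjects >= 1)
  spec <- .as_model_spec(model)
  seeds <- .derive_seeds(seed, 2 * n_subjects + 1)
  set.seed(seeds[1])
  draw_one <- function(name) {
    pr <- param_priors[[name]]
    if (is.null(pr)) stop("no prior for parameter '", name, "'", call. = FALSE)
    if (is.function(pr)) {
      for (i in seq_len(100)) {
        v <- pr(1)
        ok <- is.finite(v) &&
          !(name == "gamma" && spec$level == "punishment" && (v < 0 || v > 1)) &&
          !(name %in% c("k", "beta") && v <= 0)
        if (ok) return(v)
      }
      stop("prior for '", name, "' kept producing out-of-bounds draws",
           call. = FALSE)
    }
    stats::runif(1, pr[1], pr[2])
  }
  true <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    vapply(spec$params, draw_one, numeric(1))
  }))
  true <- as.data.frame(true)
  true$subject <- sprintf("s%02d", seq_len(n_subjects))
  datasets <- lapply(seq_len(n_subjects), function(i) {
    des <- build_design(design_spec, seed = seeds[2 * i])
    pars <- unlist(true[i, spec$params])
    simulate_choices(des, spec, pars, seed = seeds[2 * i + 1],
                     subject_id = true$subject[i], miss_rate = miss_rate)
  })
  names(datasets) <- true$subject
  attr(datasets, "true_params") <- true
  attr(datasets, "generator_model") <- spec$name
  datasets
}
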