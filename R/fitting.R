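# Per-subject estimation: penalized ML on unconstrained transforms,
# multi-start quasi-Newton, Laplace/BIC approximations to log model
# evidence.

#' Fit settings
#'
#' @param n_restarts number of optimizer starts (one central start plus
#'   dispersed random starts).
#' @param evidence `"laplace"` (default) or `"bic"`. Laplace uses weak
#'   normal priors (sd `prior_sd`) on the transformed parameters and the
#'   numeric Hessian at the posterior mode; if the Hessian is not positive
#'   definite the fit falls back to BIC and flags it. BIC evidence is
#'   `logLik - n_params/2 * log(n_trials)`.
#' @param prior_sd standard deviation of the zero-mean normal prior on each
#'   transformed parameter (logit gamma, log k, w, log beta).
#' @param optimizer method passed to [stats::optim()].
#' @param maxit maximum optimizer iterations per start.
#' @param seed seed for the dispersed starts.
#' @param fixed optional named numeric vector of parameters (natural scale)
#'   held fixed rather than estimated.
#' @return list of class `fit_control`.
#' @export
fit_control <- function(n_restarts = 10, evidence = c("laplace", "bic"),
                        prior_sd = 3, optimizer = "BFGS", maxit = 500,
                        seed = NULL, fixed = NULL) {
  structure(list(n_restarts = n_restarts, evidence = match.arg(evidence),
                 prior_sd = prior_sd, optimizer = optimizer, maxit = maxit,
                 seed = seed, fixed = fixed),
            class = "fit_control")
}

.to_unconstrained <- function(params, spec) {
  th <- params[spec$params]
  for (p in spec$params) {
    th[p] <- switch(spec$transform[[p]],
                    logit = stats::qlogis(params[[p]]),
                    log = log(params[[p]]),
                    identity = params[[p]])
  }
  th
}

.to_natural <- function(theta, spec) {
  pars <- theta[spec$params]
  for (p in spec$params) {
    pars[p] <- switch(spec$transform[[p]],
                      logit = stats::plogis(theta[[p]]),
                      log = exp(theta[[p]]),
                      identity = theta[[p]])
  }
  pars
}

# Fittable trials only: targets with a recorded response.
.prepare_dataset <- function(dataset, include_fillers = FALSE) {
  keep <- !is.na(dataset$option_chosen)
  if (!include_fillers) keep <- keep & !dataset$is_filler
  if (!any(keep)) stop("dataset has no fittable trials", call. = FALSE)
  list(trials = dataset[keep, c("condition", "sd", "x1", "x2", "x3")],
       choice = dataset$option_chosen[keep],
       options = attr(dataset, "options") %||% tpp_options(),
       multiplier = attr(dataset, "multiplier") %||% 3,
       subject = dataset$subject[which(keep)[1]] %||% "s01")
}

.nll_prepared <- function(prep, params, spec) {
  U <- .utility_matrix(prep$trials, params, spec, prep$options,
                       prep$multiplier)
  if (any(!is.finite(U))) {
    stop("non-finite utilities at trial ",
         which(rowSums(!is.finite(U)) > 0)[1], call. = FALSE)
  }
  z <- params[["beta"]] * U
  zmax <- apply(z, 1, max)
  z <- z - zmax
  lse <- log(rowSums(exp(z)))
  sum(lse - z[cbind(seq_len(nrow(z)), prep$choice)])
}

#' Negative log-likelihood of a choice dataset
#'
#' Sum of `-log` softmax probabilities of the observed choices under the
#' model. Filler trials and no-response trials are excluded.
#'
#' @param dataset a `choice_dataset`.
#' @param model a `model_spec` or name.
#' @param params named parameter vector including `beta`.
#' @param include_fillers include quasi-fair filler trials in the
#'   likelihood (off by default).
#' @return the negative log-likelihood (a non-negative number).
#' @export
negative_log_likelihood <- function(dataset, model, params,
                                    include_fillers = FALSE) {
  spec <- .as_model_spec(model)
  .check_params(params, spec)
  prep <- .prepare_dataset(dataset, include_fillers)
  .nll_prepared(prep, params, spec)
}

# central starting point on the transformed scale
.base_start <- function(spec) {
  st <- c(gamma = 0, k = log(0.1), w = 1, beta = log(0.5))
  st[spec$params]
}

#' Fit one subject
#'
#' Maximizes the penalized likelihood (equivalently, the posterior under
#' independent zero-mean normal priors on the transformed parameters) with
#' multiple optimizer starts, and computes an approximate log model
#' evidence (Laplace by default, BIC as fallback or on request).
#'
#' @param dataset a `choice_dataset` for one subject.
#' @param model a `model_spec` or name.
#' @param control a [fit_control()].
#' @return object of class `subject_fit`: estimated parameters (natural
#'   scale), `log_likelihood` (unpenalized, at the mode), `n_trials`,
#'   `evidence` and `evidence_method`, and diagnostics: `converged`,
#'   `restarts` (successful starts), `boundary` (parameters at extreme
#'   transformed values), `weakly_identified` (parameters with essentially
#'   no likelihood curvature at the mode, typical of degenerate choice
#'   data), `hessian_ok` and `hessian_condition` (condition number of the
#'   penalized Hessian).
#' @export
fit_subject <- function(dataset, model, control = fit_control()) {
  spec <- .as_model_spec(model)
  prep <- .prepare_dataset(dataset)
  n <- length(prep$choice)
  fixed <- control$fixed
  free <- setdiff(spec$params, names(fixed))
  if (!length(free)) stop("no free parameters to fit", call. = FALSE)
  sigma <- control$prior_sd
  d <- length(free)

  theta_fixed <- if (length(fixed)) {
    .to_unconstrained(unlist(fixed)[intersect(names(fixed), spec$params)],
                      structure(list(params = intersect(spec$params, names(fixed)),
                                     transform = spec$transform), class = "model_spec"))
  } else numeric(0)

  objective <- function(theta_free) {
    if (any(!is.finite(theta_free)) || any(abs(theta_free) > 50)) return(1e10)
    theta <- c(theta_free, theta_fixed)[spec$params]
    names(theta) <- spec$params
    pars <- .to_natural(theta, spec)
    val <- tryCatch(.nll_prepared(prep, pars, spec), error = function(e) 1e10)
    pen <- 0.5 * sum(theta_free^2) / sigma^2 +
      d * log(sigma * sqrt(2 * pi))
    out <- val + pen
    if (!is.finite(out)) 1e10 else out
  }

  base <- .base_start(spec)[free]
  if (!is.null(control$seed)) set.seed(control$seed)
  starts <- lapply(seq_len(control$n_restarts), function(r) {
    if (r == 1) base else base + stats::rnorm(d, 0, 1.5)
  })
  best <- NULL
  n_ok <- 0L
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, objective, method = control$optimizer,
                   control = list(maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for subject '", prep$subject,
         "', model '", spec$name, "'", call. = FALSE)
  }
  theta_hat <- best$par
  names(theta_hat) <- free
  theta_full <- c(theta_hat, theta_fixed)[spec$params]
  names(theta_full) <- spec$params
  params_hat <- .to_natural(theta_full, spec)
  ll <- -.nll_prepared(prep, params_hat, spec)

  hessian_ok <- NA
  hessian_condition <- NA_real_
  weakly_identified <- character(0)
  method <- control$evidence
  evidence <- NA_real_
  H <- tryCatch(stats::optimHess(theta_hat, objective),
                error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    eig <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    hessian_condition <- max(eig) / max(min(eig), .Machine$double.eps)
    # likelihood-only curvature: subtract the (diagonal) prior term; a
    # parameter with essentially no data curvature is unidentified by the
    # choices, typically because the data are degenerate (e.g. one option
    # chosen throughout).
    weakly_identified <- free[diag(H) - 1 / sigma^2 < 1]
  }
  if (method == "laplace") {
    ldet <- if (!is.null(H) && all(is.finite(H))) {
      dt <- determinant(H, logarithm = TRUE)
      if (dt$sign > 0) as.numeric(dt$modulus) else NA_real_
    } else NA_real_
    if (is.finite(ldet)) {
      hessian_ok <- TRUE
      evidence <- -best$value + d / 2 * log(2 * pi) - ldet / 2
    } else {
      hessian_ok <- FALSE
      method <- "bic"
    }
  }
  if (method == "bic") {
    evidence <- ll - d / 2 * log(n)
  }

  structure(list(
    subject = prep$subject,
    model = spec$name,
    params = params_hat,
    theta = theta_full,
    log_likelihood = ll,
    n_trials = n,
    evidence = evidence,
    evidence_method = method,
    converged = best$convergence == 0,
    restarts = n_ok,
    boundary = free[abs(theta_hat) > 5],
    weakly_identified = weakly_identified,
    hessian_ok = hessian_ok,
    hessian_condition = hessian_condition
  ), class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("Subject %s, model %s (%d trials)\n", x$subject, x$model,
              x$n_trials))
  print(round(x$params, 4))
  cat(sprintf("logLik %.3f, evidence (%s) %.3f, converged: %s\n",
              x$log_likelihood, x$evidence_method, x$evidence,
              x$converged))
  if (length(x$boundary)) {
    cat("boundary parameters:", paste(x$boundary, collapse = ", "), "\n")
  }
  if (length(x$weakly_identified)) {
    cat("weakly identified:", paste(x$weakly_identified, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.subject_fit <- function(object, ...) object$params

#' Fit a population under several models
#'
#' Fits every dataset under every model and assembles the subject-by-model
#' log-evidence matrix used by random-effects Bayesian model selection.
#' Per-subject failures are recorded; a subject is dropped from the
#' evidence matrix only if every model failed on it.
#'
#' @param datasets list of `choice_dataset`s (e.g. from
#'   [sample_population()]).
#' @param models character vector of model names (default: all four).
#' @param control a [fit_control()].
#' @return object of class `population_fit`: `fits` (subject x model list),
#'   `evidence` matrix, `table` (tidy per-fit data frame), `errors`.
#' @export
fit_population <- function(datasets, models = tpp_models(),
                           control = fit_control()) {
  stopifnot(length(datasets) >= 1)
  subj <- names(datasets) %||% sprintf("s%02d", seq_along(datasets))
  fits <- vector("list", length(datasets))
  names(fits) <- subj
  errors <- list()
  for (i in seq_along(datasets)) {
    fits[[i]] <- list()
    for (m in models) {
      f <- tryCatch(fit_subject(datasets[[i]], m, control),
                    error = function(e) e)
      if (inherits(f, "error")) {
        errors[[paste(subj[i], m, sep = ":")]] <- conditionMessage(f)
      } else {
        fits[[i]][[m]] <- f
      }
    }
  }
  keep <- vapply(fits, function(fl) length(fl) > 0, logical(1))
  ev <- vapply(fits[keep], function(fl) {
    vapply(models, function(m) {
      if (!is.null(fl[[m]])) fl[[m]]$evidence else NA_real_
    }, numeric(1))
  }, numeric(length(models)))
  ev <- matrix(ev, nrow = length(models),
               dimnames = list(models, subj[keep]))
  ev <- t(ev)
  tab <- do.call(rbind, lapply(fits[keep], function(fl) {
    do.call(rbind, lapply(fl, function(f) {
      row <- data.frame(subject = f$subject, model = f$model,
                        n_trials = f$n_trials,
                        log_likelihood = f$log_likelihood,
                        evidence = f$evidence,
                        evidence_method = f$evidence_method,
                        converged = f$converged)
      for (p in c("gamma", "k", "w", "beta")) {
        row[[p]] <- if (p %in% names(f$params)) f$params[[p]] else NA_real_
      }
      row
    }))
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, evidence = ev, table = tab, errors = errors,
                 models = models),
            class = "population_fit")
}

#' Subject-by-model log-evidence matrix of a population fit
#' @param fit a `population_fit`.
#' @return numeric matrix (subjects x models).
#' @export
evidence_matrix <- function(fit) {
  stopifnot(inherits(fit, "population_fit"))
  fit$evidence
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d subjects x %d models\n",
              nrow(x$evidence), length(x$models)))
  cat("mean log evidence per model:\n")
  print(round(colMeans(x$evidence, na.rm = TRUE), 2))
  if (length(x$errors)) {
    cat(length(x$errors), "fit failure(s):",
        paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
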