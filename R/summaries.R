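# Descriptive behavioral summaries and model-derived utility surfaces.

#' Mean punishment by condition, social distance and inequity level
#'
#' Cell summaries of punishment severity: within each
#' condition x social-distance x allocation cell the per-subject mean
#' punishment is computed first, then the across-subject mean, standard
#' error and subject count. Filler and no-response trials are excluded.
#'
#' @param datasets a `choice_dataset` or list of them.
#' @param collapse_conditions also return cells collapsed over the payment
#'   condition? (default `FALSE`).
#' @return data frame with columns `condition`, `sd`, `allocation` (label
#'   `"x1v x2"`), `mean_punishment`, `sem`, `n_subjects`, `n_trials`.
#' @export
punishment_summary <- function(datasets, collapse_conditions = FALSE) {
  if (inherits(datasets, "choice_dataset")) datasets <- list(datasets)
  dat <- do.call(rbind, lapply(datasets, as.data.frame))
  dat <- dat[!dat$is_filler & !is.na(dat$option_chosen), ]
  if (!nrow(dat)) stop("no fittable trials to summarize", call. = FALSE)
  dat$allocation <- paste0(dat$x1, "v", dat$x2)
  keys <- if (collapse_conditions) c("sd", "allocation") else
    c("condition", "sd", "allocation")
  # per-subject cell means, then across subjects
  subj_means <- stats::aggregate(
    dat["punishment"], dat[c("subject", keys)], mean)
  n_trials <- stats::aggregate(
    list(n_trials = dat$punishment), dat[keys], length)
  agg <- stats::aggregate(
    subj_means["punishment"], subj_means[keys],
    function(v) c(mean = mean(v),
                  sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                  n = length(v)))
  out <- cbind(agg[keys], as.data.frame(agg$punishment))
  names(out)[names(out) == "mean"] <- "mean_punishment"
  names(out)[names(out) == "n"] <- "n_subjects"
  out <- merge(out, n_trials, by = keys, sort = FALSE)
  ord <- if (collapse_conditions) order(out$allocation, out$sd) else
    order(out$condition, out$allocation, out$sd)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Utility of the best punishment option across a design grid
#'
#' For each social distance and allocation, the maximum over the option
#' grid of the model utility — the value of the utility-maximizing
#' punishment — arranged as a social-distance by allocation matrix suitable
#' for heatmap display.
#'
#' @param model a `model_spec` or name.
#' @param params named parameter vector (`beta` not needed).
#' @param sd_grid social distances (rows).
#' @param allocations two-column matrix (x1, x2) of allocations (columns).
#' @param condition `"costly"` or `"free"`.
#' @param x3 observer endowment.
#' @param options punishment option grid.
#' @param multiplier punishment multiplier.
#' @return numeric matrix `length(sd_grid)` x `nrow(allocations)`, with
#'   dimnames giving the distances and allocation labels, and the index of
#'   each cell's maximizing option in attribute `best_option`.
#' @export
utility_surface <- function(model, params,
                            sd_grid = c(1, 2, 3, 5, 10, 20, 50, 100),
                            allocations = cbind(x1 = c(90, 85, 80),
                                                x2 = c(10, 15, 20)),
                            condition = "costly", x3 = 50,
                            options = tpp_options(), multiplier = 3) {
  spec <- .as_model_spec(model)
  if (!"beta" %in% names(params)) params <- c(params, beta = 1)
  .check_params(params, spec)
  grid <- expand.grid(sd = sd_grid, alloc = seq_len(nrow(allocations)))
  trials <- data.frame(condition = condition, sd = grid$sd,
                       x1 = allocations[grid$alloc, "x1"],
                       x2 = allocations[grid$alloc, "x2"],
                       x3 = x3)
  U <- .utility_matrix(trials, params, spec, options, multiplier)
  best <- max.col(U, ties.method = "first")
  vals <- U[cbind(seq_len(nrow(U)), best)]
  m <- matrix(vals, nrow = length(sd_grid),
              dimnames = list(sd = sd_grid,
                              allocation = paste0(allocations[, "x1"], "v",
                                                  allocations[, "x2"])))
  attr(m, "best_option") <- matrix(best, nrow = length(sd_grid),
                                   dimnames = dimnames(m))
  m
}
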