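# Delimited-text readers/writers and trial-wise regressor export.

.dataset_columns <- c("subject", "session", "block", "trial", "condition",
                      "sd", "x1", "x2", "x3", "is_filler", "option_chosen",
                      "punishment")

#' Write choice datasets to tab-separated text
#'
#' One row per trial with columns subject, session, block, trial,
#' condition, sd, x1, x2, x3, is_filler, option_chosen, punishment.
#' No-response trials are written with empty choice fields.
#'
#' @param datasets a `choice_dataset` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_choice_data <- function(datasets, path) {
  if (inherits(datasets, "choice_dataset")) datasets <- list(datasets)
  dat <- do.call(rbind, lapply(datasets, as.data.frame))
  dat <- dat[, .dataset_columns]
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read choice datasets from tab-separated text
#'
#' Validates the schema written by [write_choice_data()]: known conditions,
#' social distances `>= 1`, punishment amounts in the option grid and
#' consistent with the stored option index. Rows failing validation are
#' reported with their line numbers. Missing responses load as `NA` and are
#' flagged unfittable by the likelihood functions.
#'
#' @param path input file.
#' @param options punishment option grid the choices must index into.
#' @param multiplier punishment multiplier stored with each dataset.
#' @return named list of `choice_dataset`s, one per subject.
#' @export
read_choice_data <- function(path, options = tpp_options(), multiplier = 3) {
  dat <- utils::read.delim(path, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.dataset_columns, names(dat))
  if (length(missing_cols)) {
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(dat)) + 1L  # header is line 1
  bad <- function(cond, msg) {
    if (any(cond)) {
      stop(sprintf("%s (line %s)", msg,
                   paste(line[which(cond)[seq_len(min(5, sum(cond)))]],
                         collapse = ", ")), call. = FALSE)
    }
  }
  bad(!dat$condition %in% c("costly", "free"),
      "unknown condition")
  bad(!is.finite(dat$sd) | dat$sd < 1, "social distance must be >= 1")
  answered <- !is.na(dat$option_chosen)
  bad(answered & (!dat$option_chosen %in% seq_along(options)),
      "option index outside the option grid")
  bad(answered & !is.na(dat$punishment) &
        dat$punishment != options[ifelse(answered, dat$option_chosen, 1L)],
      "punishment amount does not match the chosen option")
  bad(!is.na(dat$punishment) & !dat$punishment %in% options,
      "punishment amount not in the option grid")
  dat$is_filler <- as.logical(dat$is_filler)
  split_dat <- split(dat, dat$subject)
  out <- lapply(split_dat, function(d) {
    rownames(d) <- NULL
    attr(d, "options") <- options
    attr(d, "multiplier") <- multiplier
    class(d) <- c("choice_dataset", "data.frame")
    d
  })
  out[order(names(out))]
}

#' Export trial-wise chosen-utility regressors
#'
#' For each responded trial, the utility of the chosen option under the
#' subject's fitted parameters — the quantity used as a trial-wise
#' parametric regressor in model-based imaging analyses. Values equal
#' [option_utilities()] evaluated at the chosen option. Output is a
#' BIDS-events-like tab-separated table.
#'
#' @param dataset a `choice_dataset` for one subject.
#' @param fit the subject's `subject_fit` under the model of interest.
#' @param path optional output file; when `NULL` the table is only
#'   returned.
#' @param include_fillers include filler trials (default `TRUE`; they are
#'   flagged in the output).
#' @return data frame with columns subject, session, block, trial,
#'   condition, sd, inequity (x1 - x2), is_filler, punishment,
#'   chosen_utility.
#' @export
export_regressors <- function(dataset, fit, path = NULL,
                              include_fillers = TRUE) {
  if (!inherits(fit, "subject_fit")) {
    stop("`fit` must be a subject_fit; fit the subject first", call. = FALSE)
  }
  spec <- .as_model_spec(fit$model)
  options <- attr(dataset, "options") %||% tpp_options()
  multiplier <- attr(dataset, "multiplier") %||% 3
  keep <- !is.na(dataset$option_chosen)
  if (!include_fillers) keep <- keep & !dataset$is_filler
  d <- as.data.frame(dataset)[keep, ]
  U <- .utility_matrix(d, fit$params, spec, options, multiplier)
  chosen_u <- U[cbind(seq_len(nrow(d)), d$option_chosen)]
  out <- data.frame(subject = d$subject, session = d$session,
                    block = d$block, trial = d$trial,
                    condition = d$condition, sd = d$sd,
                    inequity = d$x1 - d$x2, is_filler = d$is_filler,
                    punishment = d$punishment,
                    chosen_utility = chosen_u)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n/a")
  }
  out
}
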