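#' Trial-level reaction-time cleaning
#'
#' Applies the three standard trial-level filters to one participant's Stroop
#' trials, in a fixed order:
#' \enumerate{
#'   \item incorrect trials are removed (error-trial RTs reflect different
#'     cognitive processing and are never analysed);
#'   \item among correct trials, RTs faster than 200 ms are removed as
#'     anticipatory errors (strictly below 200; an RT of exactly 200 ms is
#'     kept);
#'   \item among the survivors, any RT greater than the survivor mean plus
#'     four survivor standard deviations (sample SD, n-1 denominator) is
#'     removed, and the rule is re-applied to the reduced set until no RT
#'     exceeds the bound. Only the upper tail is trimmed.
#' }
#' The iteration in step 3 guarantees the audited end state: every retained RT
#' lies within four standard deviations of the retained mean.
#'
#' @param trials data.frame with columns \code{participant_id},
#'   \code{trial_index}, \code{rt_ms} (> 0) and \code{correct} (logical or
#'   0/1). All rows must share one \code{participant_id}.
#' @param min_survivors minimum retained trials for the participant to be
#'   usable downstream (default 20).
#' @return list with \code{trials} (the retained rows) and \code{report}, a
#'   one-row data.frame with counts \code{n_input},
#'   \code{n_removed_incorrect}, \code{n_removed_anticipatory},
#'   \code{n_removed_outlier}, \code{n_retained} and logical \code{usable}.
#'   The counts always conserve \code{n_input}.
#' @examples
#' tr <- data.frame(participant_id = "p1", trial_index = 1:4,
#'                  rt_ms = c(150, 500, 520, 9000),
#'                  correct = c(TRUE, TRUE, FALSE, TRUE))
#' filter_trials(tr)$report
#' @export
filter_trials <- function(trials, min_survivors = 20) {
  req <- c("participant_id", "trial_index", "rt_ms", "correct")
  if (!all(req %in% names(trials)))
    stop("trials must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) < 1) stop("need at least one trial", call. = FALSE)
  if (length(unique(trials$participant_id)) != 1L)
    stop("all trials must share one participant_id", call. = FALSE)
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be > 0", call. = FALSE)
  if (anyDuplicated(trials$trial_index))
    stop("trial_index must be unique within participant", call. = FALSE)

  n_input <- nrow(trials)
  correct <- trials[as.logical(trials$correct), , drop = FALSE]
  n_incorrect <- n_input - nrow(correct)

  kept <- correct[correct$rt_ms >= 200, , drop = FALSE]
  n_anticipatory <- nrow(correct) - nrow(kept)

  n_outlier <- 0L
  repeat {
    if (nrow(kept) < 2L) break
    bound <- mean(kept$rt_ms) + 4 * stats::sd(kept$rt_ms)
    out <- kept$rt_ms > bound
    if (!any(out)) break
    n_outlier <- n_outlier + sum(out)
    kept <- kept[!out, , drop = FALSE]
  }

  report <- data.frame(
    participant_id = trials$participant_id[1],
    n_input = n_input,
    n_removed_incorrect = n_incorrect,
    n_removed_anticipatory = n_anticipatory,
    n_removed_outlier = n_outlier,
    n_retained = nrow(kept),
    usable = nrow(kept) >= min_survivors
  )
  list(trials = kept, report = report)
}

#' Clean trials for every participant in a pooled table
#'
#' Convenience wrapper applying [filter_trials()] per participant.
#'
#' @param trials pooled trial table (multiple participants).
#' @inheritParams filter_trials
#' @return list with \code{trials} (retained rows, all participants) and
#'   \code{report} (one row per participant).
#' @export
filter_trials_all <- function(trials, min_survivors = 20) {
  parts <- split(trials, trials$participant_id)
  res <- lapply(parts, filter_trials, min_survivors = min_survivors)
  list(
    trials = do.call(rbind, c(lapply(res, `[[`, "trials"),
                              list(make.row.names = FALSE))),
    report = do.call(rbind, c(lapply(res, `[[`, "report"),
                              list(make.row.names = FALSE)))
  )
}
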