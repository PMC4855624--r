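#' Root mean square of successive N-N differences (r-MSSD)
#'
#' Time-domain heart-rate-variability index of parasympathetic (vagal)
#' influence on the heart: the square root of the mean of squared successive
#' differences of normal inter-beat (N-N) intervals, with n-1 successive
#' pairs for n intervals.
#'
#' @param nn numeric vector of N-N intervals (ms), length >= 2.
#' @return r-MSSD in ms.
#' @examples
#' rmssd(c(800, 810, 800, 810))  # 10
#' @export
rmssd <- function(nn) {
  nn <- as.numeric(nn)
  if (length(nn) < 2) stop("need at least 2 N-N intervals", call. = FALSE)
  if (anyNA(nn)) stop("N-N intervals must be non-missing", call. = FALSE)
  sqrt(mean(diff(nn)^2))
}

#' Mean of beat values inside a protocol time window
#'
#' Averages beat-level values whose timestamps fall in the half-open window
#' \code{[start, end)}, minutes from protocol start. The half-open convention
#' makes adjacent windows partition the timeline: a beat exactly on a window's
#' end boundary belongs to the next window.
#'
#' @param time_min numeric vector of beat timestamps (minutes).
#' @param values numeric vector of beat values, same length.
#' @param window length-2 numeric, \code{c(start, end)} in minutes.
#' @return arithmetic mean of the in-window values.
#' @export
period_mean <- function(time_min, values, window) {
  stopifnot(length(time_min) == length(values), length(window) == 2,
            window[2] > window[1])
  inside <- time_min >= window[1] & time_min < window[2]
  if (!any(inside))
    stop(sprintf("no beats in window [%g, %g) min", window[1], window[2]),
         call. = FALSE)
  mean(values[inside])
}

#' Periods of the stress protocol
#'
#' @return character vector of the five period labels in protocol order.
#' @export
protocol_periods <- function() {
  c("baseline", "stress", "recovery1", "recovery2", "recovery3")
}

#' Reactivity and recovery change scores
#'
#' Reactivity is the stress-period value minus the baseline value (higher =
#' greater stress response); each recovery score is the corresponding
#' recovery-period value minus baseline (larger residual deviation = slower
#' return to baseline, i.e. impaired recovery). HRV change scores are
#' computed on raw r-MSSD; any log transform is the consumer's business
#' (the repeated-measures ANOVA logs HRV, the robust regressions do not).
#'
#' @param summaries data.frame with one row per period for a single
#'   participant: columns \code{participant_id}, \code{period} (the five
#'   labels of [protocol_periods()]), \code{sbp}, \code{dbp}, \code{hr},
#'   \code{hrv_rmssd}.
#' @return one-row data.frame with columns \code{<outcome>_<response>} for
#'   outcome in sbp/dbp/hr/hrv and response in reactivity/recovery1/2/3.
#' @examples
#' s <- data.frame(participant_id = "p1", period = protocol_periods(),
#'                 sbp = c(126.88, 158.72, 137.87, 136.69, 138.00),
#'                 dbp = c(74.61, 89.57, 80.93, 80.38, 81.33),
#'                 hr = c(67.15, 76.21, 66.43, 65.34, 65.69),
#'                 hrv_rmssd = c(23.65, 18.22, 25.62, 26.43, 26.17))
#' compute_change_scores(s)$sbp_reactivity  # 31.84
#' @export
compute_change_scores <- function(summaries) {
  need <- protocol_periods()
  if (!all(need %in% summaries$period))
    stop("missing period(s): ",
         paste(setdiff(need, summaries$period), collapse = ", "),
         call. = FALSE)
  if (length(unique(summaries$participant_id)) != 1L)
    stop("one participant at a time", call. = FALSE)
  row <- function(p) summaries[match(p, summaries$period), , drop = FALSE]
  base <- row("baseline")
  out <- data.frame(participant_id = summaries$participant_id[1])
  for (oc in c("sbp", "dbp", "hr", "hrv")) {
    col <- if (oc == "hrv") "hrv_rmssd" else oc
    out[[paste0(oc, "_reactivity")]] <- row("stress")[[col]] - base[[col]]
    for (k in 1:3) {
      out[[paste0(oc, "_recovery", k)]] <-
        row(paste0("recovery", k))[[col]] - base[[col]]
    }
  }
  out
}

#' Change scores for a whole cohort
#'
#' Applies the change-score definitions per participant. A participant
#' without a baseline period is excluded outright (no delta can be formed)
#' and listed in the returned report; a participant missing only some
#' non-baseline periods keeps a row with NA for the affected responses, so
#' downstream models can drop them listwise per model rather than losing the
#' participant everywhere.
#'
#' @param summaries period-summary table for many participants (long format,
#'   one row per participant x period).
#' @return list with \code{scores} (one row per participant with a baseline;
#'   NA cells where a period was absent) and \code{excluded} (data.frame of
#'   participant ids and reasons; zero rows if none).
#' @export
compute_change_scores_all <- function(summaries) {
  parts <- split(summaries, summaries$participant_id)
  scores <- list(); excl <- list()
  for (id in names(parts)) {
    p <- parts[[id]]
    miss <- setdiff(protocol_periods(), p$period)
    if ("baseline" %in% miss) {
      excl[[id]] <- data.frame(participant_id = id,
                               reason = "missing period: baseline")
    } else if (length(miss)) {
      pad <- p[rep(match("baseline", p$period), length(miss)), ]
      pad$period <- miss
      pad[, c("sbp", "dbp", "hr", "hrv_rmssd")] <- NA_real_
      scores[[id]] <- compute_change_scores(rbind(p, pad))
      message(sprintf("participant %s: missing %s; NA change scores kept",
                      id, paste(miss, collapse = ", ")))
    } else {
      scores[[id]] <- compute_change_scores(p)
    }
  }
  list(
    scores = if (length(scores))
      do.call(rbind, c(scores, list(make.row.names = FALSE)))
    else NULL,
    excluded = if (length(excl))
      do.call(rbind, c(excl, list(make.row.names = FALSE)))
    else data.frame(participant_id = character(), reason = character())
  )
}

#' Screen change-score distributions for outliers
#'
#' Reproducible analogue of a visual distribution screen: for every
#' change-score column, observations with |z| > \code{z_cut} (z computed from
#' that column's mean and SD) are flagged. The input data are never altered;
#' this is a report, not a filter.
#'
#' @param scores change-score table from [compute_change_scores_all()].
#' @param z_cut flag threshold on |z| (default 4).
#' @return data.frame of flags with columns \code{participant_id},
#'   \code{score}, \code{value}, \code{z}; zero rows when nothing is flagged.
#' @export
screen_change_scores <- function(scores, z_cut = 4) {
  stopifnot(nrow(scores) >= 3)
  cols <- setdiff(names(scores), "participant_id")
  flags <- list()
  for (cl in cols) {
    v <- scores[[cl]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    z <- (v - mean(v, na.rm = TRUE)) / s
    hit <- which(abs(z) > z_cut)
    if (length(hit))
      flags[[cl]] <- data.frame(participant_id = scores$participant_id[hit],
                                score = cl, value = v[hit], z = z[hit])
  }
  if (length(flags))
    do.call(rbind, c(flags, list(make.row.names = FALSE)))
  else
    data.frame(participant_id = character(), score = character(),
               value = numeric(), z = numeric())
}

#' Reduce beat-level data to per-period summaries
#'
#' For each participant and each protocol period, averages beat-level SBP and
#' DBP, converts the mean N-N interval to heart rate (HR bpm = 60000 / mean
#' N-N ms) and computes r-MSSD from the N-N series.
#'
#' @param beats data.frame with columns \code{participant_id}, \code{period},
#'   \code{beat_index}, \code{nn_ms}, \code{sbp_mmHg}, \code{dbp_mmHg}.
#' @return long data.frame, one row per participant x period, with columns
#'   \code{participant_id}, \code{period}, \code{sbp}, \code{dbp}, \code{hr},
#'   \code{hrv_rmssd}.
#' @export
summarize_periods <- function(beats) {
  req <- c("participant_id", "period", "nn_ms", "sbp_mmHg", "dbp_mmHg")
  if (!all(req %in% names(beats)))
    stop("beats must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- interaction(beats$participant_id, beats$period, drop = TRUE)
  parts <- split(beats, key)
  rows <- lapply(parts, function(b) {
    data.frame(participant_id = b$participant_id[1], period = b$period[1],
               sbp = mean(b$sbp_mmHg), dbp = mean(b$dbp_mmHg),
               hr = 60000 / mean(b$nn_ms), hrv_rmssd = rmssd(b$nn_ms))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$participant_id,
            match(out$period, protocol_periods())), , drop = FALSE]
}
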