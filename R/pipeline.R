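#' Median-split dichotomisation of task ratings
#'
#' Converts 7-point Likert ratings (bimodal in practice for task difficulty
#' and involvement) into a high/low indicator by a median split: high means
#' strictly above the sample median, so ties at the median go low. The rule
#' is deterministic by construction.
#'
#' @param ratings integer vector of ratings in 1..7.
#' @return integer 0/1 vector, 1 = high.
#' @examples
#' dichotomize_rating(c(1, 2, 2, 5, 6, 7))  # 0 0 0 1 1 1
#' @export
dichotomize_rating <- function(ratings) {
  if (length(ratings) == 0) stop("empty ratings", call. = FALSE)
  if (!all(ratings %in% 1:7))
    stop("ratings must be integers in 1..7", call. = FALSE)
  as.integer(ratings > stats::median(ratings))
}

#' Build the adjusted design matrix for one regression cell
#'
#' Assembles the design for one (RT predictor, outcome, response) cell of the
#' analysis: the outcome column is the selected change score (HRV enters on
#' the raw r-MSSD scale here — the robust regressions are the exception to
#' the log-HRV convention), and the predictors are the intercept, the fitted
#' RT parameter (ms), the baseline (prestress) value of the cardiovascular
#' outcome, age, sex, BMI, employment grade as two indicator columns against
#' the reference level "higher", the number of correct Stroop trials (a
#' cognitive-ability marker) and the dichotomised task difficulty and
#' involvement ratings. Rows with any missing field are dropped (listwise
#' within each model) with the count reported.
#'
#' @param scores change-score table ([compute_change_scores_all()]).
#' @param covariates covariate table (one row per participant:
#'   \code{participant_id}, \code{age}, \code{female}, \code{bmi},
#'   \code{grade}, \code{difficulty_rating}, \code{involvement_rating}).
#' @param rt_params fitted RT parameters per participant
#'   (\code{participant_id}, \code{mu}, \code{sigma}, \code{tau},
#'   \code{n_correct}).
#' @param baselines baseline period values per participant
#'   (\code{participant_id} plus sbp/dbp/hr/hrv columns).
#' @param predictor one of "mu", "sigma", "tau".
#' @param outcome one of "sbp", "dbp", "hr", "hrv".
#' @param response one of "reactivity", "recovery1", "recovery2",
#'   "recovery3".
#' @return list with \code{X} (numeric design matrix, 11 named columns
#'   including intercept), \code{y}, \code{participant_id} and
#'   \code{n_dropped}.
#' @export
build_design <- function(scores, covariates, rt_params, baselines,
                         predictor = c("mu", "sigma", "tau"),
                         outcome = c("sbp", "dbp", "hr", "hrv"),
                         response = c("reactivity", "recovery1",
                                      "recovery2", "recovery3")) {
  predictor <- match.arg(predictor)
  outcome <- match.arg(outcome)
  response <- match.arg(response)

  cov2 <- covariates
  cov2$difficulty_high <- dichotomize_rating(cov2$difficulty_rating)
  cov2$involvement_high <- dichotomize_rating(cov2$involvement_rating)

  d <- merge(scores[, c("participant_id", paste0(outcome, "_", response))],
             cov2, by = "participant_id")
  d <- merge(d, rt_params[, c("participant_id", predictor, "n_correct")],
             by = "participant_id")
  base_col <- baselines[, c("participant_id", outcome)]
  names(base_col)[2] <- "baseline_outcome"
  d <- merge(d, base_col, by = "participant_id")

  n_before <- nrow(d)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_dropped <- n_before - nrow(d)
  if (n_dropped > 0)
    message(sprintf("%s/%s/%s: dropped %d incomplete row(s)",
                    predictor, outcome, response, n_dropped))

  X <- cbind(
    `(Intercept)` = 1,
    rt = d[[predictor]],
    baseline_outcome = d$baseline_outcome,
    age = d$age,
    female = d$female,
    bmi = d$bmi,
    grade_intermediate = as.integer(d$grade == "intermediate"),
    grade_lower = as.integer(d$grade == "lower"),
    correct_trials = d$n_correct,
    difficulty_high = d$difficulty_high,
    involvement_high = d$involvement_high
  )
  if (nrow(X) < ncol(X) + 5)
    stop(sprintf("too few complete rows (%d) for %d predictors",
                 nrow(X), ncol(X)), call. = FALSE)
  list(X = X, y = d[[paste0(outcome, "_", response)]],
       participant_id = d$participant_id, n_dropped = n_dropped)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate -> clean -> fit -> summarise -> ANOVA -> regress:
#' simulates (or accepts) a cohort, applies the trial filters per
#' participant, fits the ex-Gaussian by maximum likelihood to each usable
#' participant's cleaned RTs, reduces beat data to the five period summaries
#' and the reactivity/recovery change scores, screens the change-score
#' distributions, runs the repeated-measures ANOVA (log HRV) per outcome,
#' and fits the 48 adjusted SMDM regressions (3 RT predictors x 4 outcomes x
#' 4 responses). Deterministic given \code{config$seed}.
#'
#' @param config a [cohort_config()].
#' @param cohort optionally, an already-simulated cohort (then \code{config}
#'   is taken from it).
#' @param reg_config an [smdm_config()]; its seed defaults to the cohort
#'   seed.
#' @param min_survivors minimum cleaned trials for a participant's RT fit.
#' @return object of class \code{"analysis_report"}: list with
#'   \code{regressions} (48-row data.frame: predictor, outcome, response, n,
#'   B, SE, p, r2, converged, sig annotation), \code{anova} (list of
#'   [rm_anova()] results per outcome), \code{filter_report},
#'   \code{rt_params}, \code{summaries}, \code{scores}, \code{screen},
#'   \code{excluded}, \code{provenance}.
#' @export
run_full_analysis <- function(config = cohort_config(), cohort = NULL,
                              reg_config = NULL, min_survivors = 20) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  config <- cohort$config
  if (is.null(reg_config)) reg_config <- smdm_config(seed = config$seed)

  cleaned <- filter_trials_all(cohort$trials, min_survivors = min_survivors)
  rep <- cleaned$report
  usable <- rep$participant_id[rep$usable]
  if (length(usable) < length(unique(cohort$trials$participant_id)))
    message(sprintf("stage rt_clean: %d participant(s) unusable (< %d trials)",
                    length(unique(cohort$trials$participant_id)) -
                      length(usable), min_survivors))

  fits <- lapply(usable, function(id) {
    rts <- cleaned$trials$rt_ms[cleaned$trials$participant_id == id]
    f <- tryCatch(fit_exgauss(rts, min_n = min_survivors),
                  error = function(e) {
                    stop(sprintf("stage fit-rt failed for participant %s: %s",
                                 id, conditionMessage(e)), call. = FALSE)
                  })
    i <- match(id, rep$participant_id)
    data.frame(participant_id = id, mu = f$mu, sigma = f$sigma, tau = f$tau,
               n_used = f$n_used, converged = f$converged,
               n_correct = rep$n_input[i] - rep$n_removed_incorrect[i])
  })
  rt_params <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  if (any(!rt_params$converged))
    message(sprintf("stage fit-rt: %d non-converged fit(s)",
                    sum(!rt_params$converged)))

  summaries <- summarize_periods(cohort$beats)
  cs <- compute_change_scores_all(summaries)
  scores <- cs$scores
  screen <- screen_change_scores(scores)
  if (nrow(screen))
    message(sprintf("screen: %d change score(s) flagged at |z| > 4",
                    nrow(screen)))

  anova_res <- list()
  for (oc in CV_OUTCOMES) {
    col <- if (oc == "hrv") "hrv_rmssd" else oc
    wide <- stats::reshape(
      summaries[, c("participant_id", "period", col)],
      idvar = "participant_id", timevar = "period", direction = "wide")
    mat <- as.matrix(wide[, paste(col, protocol_periods(), sep = ".")])
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    anova_res[[oc]] <- rm_anova(mat, outcome = oc,
                                log_transform = (oc == "hrv"))
  }

  baselines <- summaries[summaries$period == "baseline",
                         c("participant_id", "sbp", "dbp", "hr")]
  hrvb <- summaries[summaries$period == "baseline",
                    c("participant_id", "hrv_rmssd")]
  names(hrvb)[2] <- "hrv"
  baselines <- merge(baselines, hrvb, by = "participant_id")

  cells <- list()
  for (pred in c("mu", "sigma", "tau")) {
    for (oc in CV_OUTCOMES) {
      for (resp in CV_RESPONSES) {
        des <- build_design(scores, cohort$covariates, rt_params, baselines,
                            predictor = pred, outcome = oc, response = resp)
        fit <- fit_smdm(des$X, des$y, reg_config)
        p <- fit$p_value[["rt"]]
        cells[[length(cells) + 1L]] <- data.frame(
          predictor = pred, outcome = oc, response = resp,
          n = fit$n, B = fit$coefficients[["rt"]], SE = fit$se[["rt"]],
          p = p, r2 = fit$r2, converged = fit$converged,
          sig = if (p <= 0.05) "*" else if (p <= 0.09) "**" else "")
      }
    }
  }
  regressions <- do.call(rbind, c(cells, list(make.row.names = FALSE)))

  structure(list(
    regressions = regressions, anova = anova_res,
    filter_report = rep, rt_params = rt_params, summaries = summaries,
    scores = scores, screen = screen, excluded = cs$excluded,
    provenance = list(seed = config$seed,
                      n_participants = config$n_participants,
                      package_version =
                        as.character(utils::packageVersion("exgstress")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report: RT predictors of cardiovascular stress responses\n")
  cat(sprintf("  cohort n = %d (seed %d); %d usable RT fits\n\n",
              x$provenance$n_participants, x$provenance$seed,
              nrow(x$rt_params)))
  cat("Repeated-measures ANOVA, main effect of protocol period:\n")
  for (a in x$anova) print(a)
  cat("\nRobust regressions (B +/- SE, R2); * p <= .05, ** p <= .09:\n")
  tab <- x$regressions
  tab$cell <- sprintf("%8.5f +/- %7.5f %-2s R2=%.2f",
                      tab$B, tab$SE, tab$sig, tab$r2)
  print(tab[, c("predictor", "outcome", "response", "n", "cell")],
        row.names = FALSE)
  invisible(x)
}

#' Write the regression report as delimited text
#'
#' @param report an \code{"analysis_report"}.
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$regressions, path, row.names = FALSE)
  invisible(path)
}
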