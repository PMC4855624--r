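CV_OUTCOMES <- c("sbp", "dbp", "hr", "hrv")
CV_RESPONSES <- c("reactivity", "recovery1", "recovery2", "recovery3")

.named_mat <- function(values) {
  matrix(values, nrow = 4, byrow = TRUE,
         dimnames = list(CV_OUTCOMES, CV_RESPONSES))
}

#' Synthetic cohort configuration
#'
#' Builds the configuration object driving the seeded synthetic-cohort
#' generator. The defaults emulate a healthy older cohort undergoing a
#' 5-period acute mental-stress protocol: a 30-min seated rest whose last 5
#' minutes provide baseline values, a 5-min stress task, and three 5-min
#' recovery windows at 15-20, 40-45 and 70-75 min post-stress. Reaction-time
#' trials come from participant-specific ex-Gaussian distributions sampled
#' over a fixed 5-min task, with a 63.64% correct rate and a small injected
#' fraction of sub-200 ms anticipatory responses. Per-period cardiovascular
#' change scores are baseline + a population period shift + configured linear
#' effects of the participant's centred RT parameters + Gaussian noise, so
#' downstream regressions have known ground truth.
#'
#' Between-subject RT parameters are drawn lognormally (guaranteeing
#' positivity), moment-matched so the configured \code{mean}/\code{sd} are
#' the distribution's actual mean and SD; with the defaults the population
#' mean RT is \code{mu + tau = 2344.21 ms}.
#'
#' @param n_participants cohort size (default 262).
#' @param seed integer master seed; every generated quantity derives from it.
#' @param rt_pop list with elements \code{mu}, \code{sigma}, \code{tau}, each
#'   \code{c(mean =, sd =)} in ms, between-subject distribution of the
#'   ex-Gaussian parameters.
#' @param p_correct per-trial probability of a correct response, in (0, 1).
#' @param anticipatory_frac fraction of trials replaced by sub-200 ms
#'   anticipatory responses (exercises the cleaning filter).
#' @param task_duration_s RT task duration (s); trials accumulate until their
#'   cumulative RT + stimulus time fills it, so trial counts vary across
#'   participants.
#' @param stimulus_s fixed per-trial stimulus presentation time (s).
#' @param protocol named list of 5 half-open period windows,
#'   \code{c(start, end)} in minutes from protocol start.
#' @param cv_baseline_pop list with \code{sbp}, \code{dbp}, \code{hr},
#'   \code{hrv}, each \code{c(mean =, sd =)} (mmHg / bpm / ms r-MSSD).
#' @param period_deltas 4 x 4 matrix (outcome x response) of population mean
#'   change scores relative to baseline.
#' @param effects list with matrices \code{mu}, \code{sigma}, \code{tau}
#'   (outcome x response): linear coefficient of the centred RT parameter on
#'   each change score, outcome units per ms. Defaults inject effects through
#'   tau only.
#' @param noise_sd 4 x 4 matrix of residual SDs per change score.
#' @param covariate_pop list: \code{age} \code{c(mean, sd)},
#'   \code{p_female}, \code{bmi} \code{c(mean, sd)}, \code{grade_probs}
#'   (named, higher/intermediate/lower), \code{rating_probs} (length 7,
#'   bimodal by default, shared by difficulty and involvement ratings).
#' @param bp_beat_noise_sd beat-level SD of SBP/DBP around the period mean
#'   (mmHg).
#' @return validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(
    n_participants = 262L,
    seed = 1L,
    rt_pop = list(mu = c(mean = 1944.21, sd = 250),
                  sigma = c(mean = 300, sd = 100),
                  tau = c(mean = 400, sd = 250)),
    p_correct = 0.6364,
    anticipatory_frac = 0.02,
    task_duration_s = 300,
    stimulus_s = 0.5,
    protocol = list(baseline = c(25, 30), stress = c(30, 35),
                    recovery1 = c(50, 55), recovery2 = c(75, 80),
                    recovery3 = c(105, 110)),
    cv_baseline_pop = list(sbp = c(mean = 126.88, sd = 16.1),
                           dbp = c(mean = 74.61, sd = 10.3),
                           hr = c(mean = 67.15, sd = 8.8),
                           hrv = c(mean = 23.65, sd = 13.5)),
    period_deltas = .named_mat(c(31.84, 10.99,  9.81, 11.12,
                                 14.96,  6.32,  5.77,  6.72,
                                  9.06, -0.72, -1.81, -1.46,
                                 -5.43,  1.97,  2.78,  2.52)),
    effects = list(mu = .named_mat(rep(0, 16)),
                   sigma = .named_mat(rep(0, 16)),
                   tau = .named_mat(c(-0.009, -0.007, -0.006,  -0.006,
                                      -0.0004, -0.0023, -0.00192, -0.00159,
                                      -0.0030, -0.0005,  0.0001,  0.00056,
                                      -0.0038, -0.0003, -0.0047, -0.0029))),
    noise_sd = .named_mat(c(12, 9, 9, 9,
                             7, 5, 5, 5,
                             6, 4, 4, 4,
                             8, 6, 6, 6)),
    covariate_pop = list(age = c(mean = 63.3, sd = 5.5),
                         p_female = 0.611,
                         bmi = c(mean = 25.7, sd = 4.0),
                         grade_probs = c(higher = 0.286,
                                         intermediate = 0.416,
                                         lower = 0.298),
                         rating_probs = c(0.05, 0.20, 0.15, 0.05,
                                          0.15, 0.25, 0.15)),
    bp_beat_noise_sd = 5) {
  cfg <- structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    rt_pop = rt_pop, p_correct = p_correct,
    anticipatory_frac = anticipatory_frac,
    task_duration_s = task_duration_s, stimulus_s = stimulus_s,
    protocol = protocol, cv_baseline_pop = cv_baseline_pop,
    period_deltas = period_deltas, effects = effects, noise_sd = noise_sd,
    covariate_pop = covariate_pop, bp_beat_noise_sd = bp_beat_noise_sd
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  fail <- function(field, why)
    stop(sprintf("invalid cohort config field '%s': %s", field, why),
         call. = FALSE)
  if (config$n_participants < 1) fail("n_participants", "must be >= 1")
  if (!(config$p_correct > 0 && config$p_correct < 1))
    fail("p_correct", "must lie in (0, 1)")
  for (p in c("mu", "sigma", "tau")) {
    v <- config$rt_pop[[p]]
    if (is.null(v) || anyNA(v[c("mean", "sd")]))
      fail(paste0("rt_pop$", p), "needs named mean and sd")
    if (p != "mu" && v[["mean"]] <= 0)
      fail(paste0("rt_pop$", p), "population mean must be > 0")
    if (v[["sd"]] < 0) fail(paste0("rt_pop$", p), "sd must be >= 0")
  }
  if (config$anticipatory_frac < 0 || config$anticipatory_frac >= 1)
    fail("anticipatory_frac", "must lie in [0, 1)")
  if (config$task_duration_s <= 0) fail("task_duration_s", "must be > 0")
  if (!identical(sort(names(config$protocol)), sort(protocol_periods())))
    fail("protocol", "must name exactly the five protocol periods")
  for (pd in names(config$protocol)) {
    w <- config$protocol[[pd]]
    if (length(w) != 2 || w[2] <= w[1])
      fail(paste0("protocol$", pd), "window must be c(start, end), end > start")
  }
  for (oc in CV_OUTCOMES) {
    v <- config$cv_baseline_pop[[oc]]
    if (is.null(v) || v[["mean"]] <= 0)
      fail(paste0("cv_baseline_pop$", oc), "mean must be > 0")
    if (v[["sd"]] < 0)
      fail(paste0("cv_baseline_pop$", oc), "sd must be >= 0")
  }
  if (any(config$noise_sd < 0)) fail("noise_sd", "must be >= 0")
  if (config$bp_beat_noise_sd < 0) fail("bp_beat_noise_sd", "must be >= 0")
  gp <- config$covariate_pop$grade_probs
  if (abs(sum(gp) - 1) > 1e-6) fail("covariate_pop$grade_probs",
                                    "must sum to 1")
  invisible(TRUE)
}

# lognormal draws moment-matched to a target mean and sd (sd 0 -> constant)
.rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- base::log(1 + sd^2 / mean^2)
  stats::rlnorm(n, meanlog = base::log(mean) - sdlog2 / 2,
                sdlog = sqrt(sdlog2))
}

.participant_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * i) %% 2147483629)
}

#' Generate participant-level ground truth
#'
#' Draws each participant's true ex-Gaussian parameters (lognormal between
#' subjects, so always positive), covariates, baseline cardiovascular values
#' and per-period cardiovascular targets. Non-baseline period targets are
#' baseline + configured population delta + configured linear effects of the
#' centred RT parameters + Gaussian noise, which makes every change score's
#' regression structure known exactly.
#'
#' @param config a [cohort_config()].
#' @return list of class \code{"cohort_truth"}: \code{participants} (one row
#'   per participant: id, mu, sigma, tau, covariates) and
#'   \code{period_values} (long, one row per participant x period: sbp, dbp,
#'   hr, hrv targets).
#' @export
generate_participants <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  withr::with_seed(config$seed, {
    ids <- sprintf("p%04d", seq_len(n))
    mu <- .rlnorm_ms(n, config$rt_pop$mu[["mean"]], config$rt_pop$mu[["sd"]])
    sigma <- .rlnorm_ms(n, config$rt_pop$sigma[["mean"]],
                        config$rt_pop$sigma[["sd"]])
    tau <- .rlnorm_ms(n, config$rt_pop$tau[["mean"]],
                      config$rt_pop$tau[["sd"]])
    cp <- config$covariate_pop
    participants <- data.frame(
      participant_id = ids, mu = mu, sigma = sigma, tau = tau,
      age = stats::rnorm(n, cp$age[["mean"]], cp$age[["sd"]]),
      female = stats::rbinom(n, 1, cp$p_female),
      bmi = pmax(stats::rnorm(n, cp$bmi[["mean"]], cp$bmi[["sd"]]), 14),
      grade = sample(names(cp$grade_probs), n, replace = TRUE,
                     prob = cp$grade_probs),
      difficulty_rating = sample(1:7, n, replace = TRUE,
                                 prob = cp$rating_probs),
      involvement_rating = sample(1:7, n, replace = TRUE,
                                  prob = cp$rating_probs)
    )

    centred <- list(mu = mu - config$rt_pop$mu[["mean"]],
                    sigma = sigma - config$rt_pop$sigma[["mean"]],
                    tau = tau - config$rt_pop$tau[["mean"]])
    base_vals <- list(
      sbp = pmax(stats::rnorm(n, config$cv_baseline_pop$sbp[["mean"]],
                              config$cv_baseline_pop$sbp[["sd"]]), 70),
      dbp = pmax(stats::rnorm(n, config$cv_baseline_pop$dbp[["mean"]],
                              config$cv_baseline_pop$dbp[["sd"]]), 40),
      hr = pmax(stats::rnorm(n, config$cv_baseline_pop$hr[["mean"]],
                             config$cv_baseline_pop$hr[["sd"]]), 35),
      hrv = .rlnorm_ms(n, config$cv_baseline_pop$hrv[["mean"]],
                       config$cv_baseline_pop$hrv[["sd"]])
    )

    periods <- protocol_periods()
    rows <- vector("list", length(periods))
    names(rows) <- periods
    rows$baseline <- data.frame(participant_id = ids, period = "baseline",
                                sbp = base_vals$sbp, dbp = base_vals$dbp,
                                hr = base_vals$hr, hrv = base_vals$hrv)
    resp_of <- c(stress = "reactivity", recovery1 = "recovery1",
                 recovery2 = "recovery2", recovery3 = "recovery3")
    for (pd in names(resp_of)) {
      resp <- resp_of[[pd]]
      vals <- list()
      for (oc in CV_OUTCOMES) {
        eff <- config$effects$mu[oc, resp] * centred$mu +
          config$effects$sigma[oc, resp] * centred$sigma +
          config$effects$tau[oc, resp] * centred$tau
        v <- base_vals[[oc]] + config$period_deltas[oc, resp] + eff +
          stats::rnorm(n, 0, config$noise_sd[oc, resp])
        floor_v <- switch(oc, sbp = 60, dbp = 35, hr = 30, hrv = 1)
        vals[[oc]] <- pmax(v, floor_v)
      }
      rows[[pd]] <- data.frame(participant_id = ids, period = pd,
                               sbp = vals$sbp, dbp = vals$dbp,
                               hr = vals$hr, hrv = vals$hrv)
    }
    structure(list(
      participants = participants,
      period_values = do.call(rbind, c(rows, list(make.row.names = FALSE)))
    ), class = "cohort_truth")
  })
}

#' Generate one participant's reaction-time trials
#'
#' Samples trial RTs from the participant's ex-Gaussian distribution until
#' the cumulative trial time (RT plus fixed stimulus time) fills the task
#' duration, so trial counts vary across participants with their speed. A
#' configured fraction of trials is replaced by sub-200 ms anticipatory
#' responses, and each trial is independently flagged correct with the
#' configured probability.
#'
#' @param truth one row of \code{generate_participants()$participants}.
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to a participant-specific stream
#'   derived from \code{config$seed} and the participant id.
#' @return data.frame with columns \code{participant_id}, \code{trial_index},
#'   \code{rt_ms}, \code{correct}.
#' @export
generate_rt_trials <- function(truth, config, seed = NULL) {
  validate_cohort_config(config)
  if (config$task_duration_s <= 0)
    stop("task duration must be positive", call. = FALSE)
  if (is.null(seed)) {
    i <- as.integer(sub("^p", "", truth$participant_id))
    seed <- .participant_seed(config$seed, i)
  }
  withr::with_seed(seed, {
    budget_ms <- config$task_duration_s * 1000
    per_trial_overhead <- config$stimulus_s * 1000
    exp_trial <- truth$mu + truth$tau + per_trial_overhead
    rts <- numeric(0)
    repeat {
      m <- max(20L, ceiling(2 * budget_ms / exp_trial))
      batch <- stats::rnorm(m, truth$mu, truth$sigma) +
        stats::rexp(m, rate = 1 / truth$tau)
      antic <- stats::runif(m) < config$anticipatory_frac
      batch[antic] <- stats::runif(sum(antic), 80, 199)
      batch <- pmax(batch, 1)
      rts <- c(rts, batch)
      if (sum(rts + per_trial_overhead) > budget_ms) break
    }
    n_fit <- findInterval(budget_ms, cumsum(rts + per_trial_overhead)) + 1L
    n_fit <- min(n_fit, length(rts))
    rts <- rts[seq_len(n_fit)]
    data.frame(participant_id = truth$participant_id,
               trial_index = seq_len(n_fit),
               rt_ms = rts,
               correct = stats::runif(n_fit) < config$p_correct)
  })
}

#' Generate one participant's beat-level cardiovascular series
#'
#' For each protocol period, emits an N-N interval series whose mean matches
#' the participant's period heart-rate target (N-N ms = 60000 / HR bpm) and
#' whose i.i.d. beat-level jitter is scaled so the expected r-MSSD matches
#' the period's HRV target (jitter SD = target r-MSSD / sqrt(2), since
#' successive differences of i.i.d. noise have variance 2 SD^2). Beat-level
#' SBP/DBP values are the period targets plus Gaussian noise. Timestamps are
#' minutes from protocol start, inside the period's window.
#'
#' @param truth_periods rows of \code{generate_participants()$period_values}
#'   for one participant.
#' @inheritParams generate_rt_trials
#' @return data.frame with columns \code{participant_id}, \code{period},
#'   \code{beat_index}, \code{time_min}, \code{nn_ms}, \code{sbp_mmHg},
#'   \code{dbp_mmHg}.
#' @export
generate_cardio_series <- function(truth_periods, config, seed = NULL) {
  validate_cohort_config(config)
  id <- truth_periods$participant_id[1]
  if (is.null(seed)) {
    i <- as.integer(sub("^p", "", id))
    seed <- .participant_seed(config$seed + 104729, i)
  }
  withr::with_seed(seed, {
    out <- vector("list", nrow(truth_periods))
    for (j in seq_len(nrow(truth_periods))) {
      row <- truth_periods[j, ]
      window <- config$protocol[[row$period]]
      window_ms <- (window[2] - window[1]) * 60000
      mean_nn <- 60000 / row$hr
      jitter_sd <- row$hrv / sqrt(2)
      n_beats <- ceiling(window_ms / mean_nn) + 10L
      nn <- pmax(mean_nn + stats::rnorm(n_beats, 0, jitter_sd), 1)
      t_min <- window[1] + cumsum(nn) / 60000
      keep <- t_min < window[2]
      nn <- nn[keep]; t_min <- t_min[keep]
      nb <- length(nn)
      out[[j]] <- data.frame(
        participant_id = id, period = row$period,
        beat_index = seq_len(nb), time_min = t_min, nn_ms = nn,
        sbp_mmHg = row$sbp + stats::rnorm(nb, 0, config$bp_beat_noise_sd),
        dbp_mmHg = row$dbp + stats::rnorm(nb, 0, config$bp_beat_noise_sd))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs [generate_participants()], then [generate_rt_trials()] and
#' [generate_cardio_series()] for every participant, returning all tables the
#' analysis pipeline consumes. Deterministic given \code{config$seed}.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; when given, writes \code{trials.csv},
#'   \code{beats.csv}, \code{covariates.csv} and \code{config.yaml} there.
#' @return list of class \code{"cohort"}: \code{truth} (the
#'   \code{cohort_truth}), \code{trials}, \code{beats}, \code{covariates},
#'   \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL) {
  truth <- generate_participants(config)
  n <- config$n_participants
  trials <- vector("list", n); beats <- vector("list", n)
  pv <- split(truth$period_values, truth$period_values$participant_id)
  for (i in seq_len(n)) {
    p <- truth$participants[i, ]
    trials[[i]] <- generate_rt_trials(p, config)
    beats[[i]] <- generate_cardio_series(pv[[p$participant_id]], config)
  }
  covars <- truth$participants[, c("participant_id", "age", "female", "bmi",
                                   "grade", "difficulty_rating",
                                   "involvement_rating")]
  cohort <- structure(list(
    truth = truth,
    trials = do.call(rbind, c(trials, list(make.row.names = FALSE))),
    beats = do.call(rbind, c(beats, list(make.row.names = FALSE))),
    covariates = covars,
    config = config
  ), class = "cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @rdname simulate_cohort
#' @param cohort a simulated cohort.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$beats, file.path(dir, "beats.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  writeLines(dump_config(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialise / restore a cohort configuration
#'
#' @param config a [cohort_config()].
#' @return \code{dump_config}: YAML text; \code{load_config}: a validated
#'   \code{cohort_config} rebuilt from YAML (file path or text).
#' @export
dump_config <- function(config = cohort_config()) {
  ser <- unclass(config)
  ser$period_deltas <- as.data.frame(ser$period_deltas)
  ser$noise_sd <- as.data.frame(ser$noise_sd)
  ser$effects <- lapply(ser$effects, as.data.frame)
  # named atomic vectors serialise as YAML maps only as lists
  ser$rt_pop <- lapply(ser$rt_pop, as.list)
  ser$cv_baseline_pop <- lapply(ser$cv_baseline_pop, as.list)
  ser$covariate_pop$age <- as.list(ser$covariate_pop$age)
  ser$covariate_pop$bmi <- as.list(ser$covariate_pop$bmi)
  ser$covariate_pop$grade_probs <- as.list(ser$covariate_pop$grade_probs)
  yaml::as.yaml(ser, precision = 12)
}

#' @rdname dump_config
#' @param path YAML file path (or a single YAML string).
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  to_mat <- function(df) {
    m <- as.matrix(as.data.frame(df))
    rownames(m) <- CV_OUTCOMES
    m[, CV_RESPONSES, drop = FALSE]
  }
  num <- function(x) {
    v <- unlist(x)
    stats::setNames(as.numeric(v), names(v))
  }
  cohort_config(
    n_participants = raw$n_participants, seed = raw$seed,
    rt_pop = lapply(raw$rt_pop, num),
    p_correct = raw$p_correct,
    anticipatory_frac = raw$anticipatory_frac,
    task_duration_s = raw$task_duration_s, stimulus_s = raw$stimulus_s,
    protocol = lapply(raw$protocol, as.numeric),
    cv_baseline_pop = lapply(raw$cv_baseline_pop, num),
    period_deltas = to_mat(raw$period_deltas),
    effects = lapply(raw$effects, to_mat),
    noise_sd = to_mat(raw$noise_sd),
    covariate_pop = list(
      age = num(raw$covariate_pop$age),
      p_female = raw$covariate_pop$p_female,
      bmi = num(raw$covariate_pop$bmi),
      grade_probs = num(raw$covariate_pop$grade_probs),
      rating_probs = as.numeric(unlist(raw$covariate_pop$rating_probs))),
    bp_beat_noise_sd = raw$bp_beat_noise_sd)
}
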