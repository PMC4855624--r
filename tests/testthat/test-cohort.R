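test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(p_correct = 1.2), "p_correct")
  expect_error(cohort_config(rt_pop = list(mu = c(mean = 2000, sd = 100),
                                           sigma = c(mean = -3, sd = 10),
                                           tau = c(mean = 400, sd = 100))),
               "rt_pop\\$sigma")
  expect_error(cohort_config(task_duration_s = -1), "task_duration_s")
  expect_error(cohort_config(protocol = list(baseline = c(5, 1))),
               "protocol")
})

test_that("the generator is deterministic given the seed", {
  cfg <- cohort_config(n_participants = 6, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$beats, c2$beats)
  expect_identical(c1$truth$participants, c2$truth$participants)
  # different seed, different cohort
  c3 <- simulate_cohort(cohort_config(n_participants = 6, seed = 12))
  expect_false(identical(c1$trials$rt_ms, c3$trials$rt_ms))
})

test_that("zero effects and zero noise give exactly the configured deltas", {
  cfg <- cohort_config(
    n_participants = 40, seed = 5,
    effects = list(mu = matrix(0, 4, 4, dimnames = dimnames(cohort_config()$noise_sd)),
                   sigma = matrix(0, 4, 4, dimnames = dimnames(cohort_config()$noise_sd)),
                   tau = matrix(0, 4, 4, dimnames = dimnames(cohort_config()$noise_sd))),
    noise_sd = matrix(0, 4, 4, dimnames = dimnames(cohort_config()$noise_sd)),
    cv_baseline_pop = list(sbp = c(mean = 126.88, sd = 10),
                           dbp = c(mean = 74.61, sd = 6),
                           hr = c(mean = 67.15, sd = 6),
                           hrv = c(mean = 30, sd = 5)))
  truth <- generate_participants(cfg)
  pv <- truth$period_values
  base <- pv[pv$period == "baseline", ]
  for (pd in c("stress", "recovery1", "recovery2", "recovery3")) {
    resp <- if (pd == "stress") "reactivity" else pd
    cur <- pv[pv$period == pd, ]
    for (oc in c("sbp", "dbp", "hr", "hrv")) {
      expect_equal(cur[[oc]] - base[[oc]],
                   rep(cfg$period_deltas[oc, resp], nrow(base)),
                   tolerance = 1e-12)
    }
  }
})

test_that("baseline cardiovascular draws match the configured population", {
  truth <- generate_participants(cohort_config(n_participants = 5000,
                                               seed = 101))
  base <- truth$period_values[truth$period_values$period == "baseline", ]
  expect_equal(mean(base$sbp), 126.9, tolerance = 0.5 / 126.9)
  expect_lt(abs(mean(base$sbp) - 126.9), 0.5)
  expect_equal(sd(base$sbp), 16.1, tolerance = 0.05)
  expect_equal(mean(base$hrv), 23.65, tolerance = 0.05)
  # RT parameters positive and moment-matched
  p <- truth$participants
  expect_true(all(p$sigma > 0 & p$tau > 0))
  expect_equal(mean(p$mu + p$tau), 2344.21, tolerance = 0.02)
  expect_equal(sd(p$tau), 250, tolerance = 0.1)
})

test_that("trial generation fills the task duration and flags correctness", {
  cfg <- cohort_config(seed = 7)
  truth <- data.frame(participant_id = "p0001", mu = 1944, sigma = 300,
                      tau = 400)
  tr <- generate_rt_trials(truth, cfg, seed = 3)
  # cumulative time (RT + stimulus) brackets the 5-min budget
  tot <- cumsum(tr$rt_ms + cfg$stimulus_s * 1000)
  expect_lte(tot[nrow(tr) - 1], 300000)
  expect_gt(tot[nrow(tr)], 300000)
  expect_true(all(tr$rt_ms > 0))
  expect_identical(tr, generate_rt_trials(truth, cfg, seed = 3))

  # all-correct limit
  cfg1 <- cohort_config(p_correct = 0.999999, anticipatory_frac = 0, seed = 7)
  tr1 <- generate_rt_trials(truth, cfg1, seed = 4)
  expect_true(all(tr1$correct))

  # pooled correct fraction near the configured rate
  cfgL <- cohort_config(task_duration_s = 60000, anticipatory_frac = 0,
                        seed = 7)
  trL <- generate_rt_trials(truth, cfgL, seed = 5)
  expect_gt(nrow(trL), 15000)
  expect_equal(mean(trL$correct), 0.6364, tolerance = 0.01 / 0.6364)
  # pooled mean RT near mu + tau
  expect_equal(mean(trL$rt_ms), 2344, tolerance = 0.02)
})

test_that("beat series hit their HR and r-MSSD targets", {
  cfg <- cohort_config(seed = 13,
                       protocol = list(baseline = c(0, 170),
                                       stress = c(170, 175),
                                       recovery1 = c(190, 195),
                                       recovery2 = c(215, 220),
                                       recovery3 = c(245, 250)))
  periods <- data.frame(participant_id = "p0001",
                        period = c("baseline", "stress", "recovery1",
                                   "recovery2", "recovery3"),
                        sbp = 126, dbp = 74,
                        hr = c(60, 76, 66, 65, 65),
                        hrv = c(23.7, 18, 25, 26, 26))
  beats <- generate_cardio_series(periods, cfg, seed = 2)
  b <- beats[beats$period == "baseline", ]
  expect_gt(nrow(b), 9000)
  expect_equal(mean(b$nn_ms), 1000, tolerance = 0.01)
  expect_equal(rmssd(b$nn_ms), 23.7, tolerance = 0.05)
  expect_true(all(beats$nn_ms > 0))
  # timestamps stay inside the period window
  expect_true(all(b$time_min >= 0 & b$time_min < 170))

  # zero HRV target -> constant series -> r-MSSD 0
  periods0 <- periods; periods0$hrv <- 0
  b0 <- generate_cardio_series(periods0, cfg, seed = 2)
  expect_equal(rmssd(b0$nn_ms[b0$period == "stress"]), 0)
})

test_that("injected effects are recoverable from the ground truth", {
  cfg <- cohort_config(n_participants = 4000, seed = 17)
  truth <- generate_participants(cfg)
  pv <- truth$period_values
  delta <- pv$sbp[pv$period == "stress"] - pv$sbp[pv$period == "baseline"]
  p <- truth$participants
  fit <- lm(delta ~ p$mu + p$sigma + p$tau)
  est <- coef(fit)[["p$tau"]]
  se <- summary(fit)$coefficients["p$tau", "Std. Error"]
  expect_lt(abs(est - (-0.009)), 3 * se)
})

test_that("cohort tables round-trip through CSV and the config through YAML", {
  cfg <- cohort_config(n_participants = 4, seed = 23)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv", "beats.csv",
                                               "covariates.csv",
                                               "config.yaml")))))
  tr <- read.csv(file.path(dir, "trials.csv"))
  expect_equal(tr$rt_ms, co$trials$rt_ms, tolerance = 1e-10)

  cfg2 <- load_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$rt_pop, cfg$rt_pop)
  expect_equal(cfg2$period_deltas, cfg$period_deltas)
  expect_equal(cfg2$effects$tau, cfg$effects$tau)
  expect_identical(simulate_cohort(cfg2)$trials$rt_ms, co$trials$rt_ms)
})
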