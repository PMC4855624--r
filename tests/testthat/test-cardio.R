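test_that("r-MSSD matches hand values and a brute-force oracle", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 810, 800, 810)), 10)

  for (seed in 1:10) {
    nn <- withr::with_seed(seed, 800 + rnorm(200, 0, 30))
    acc <- 0
    for (i in 2:length(nn)) acc <- acc + (nn[i] - nn[i - 1])^2
    oracle <- sqrt(acc / (length(nn) - 1))
    expect_equal(rmssd(nn), oracle, tolerance = 1e-12)
    # shift invariance
    expect_equal(rmssd(nn + 250), rmssd(nn), tolerance = 1e-12)
  }
  expect_error(rmssd(800), "at least 2")
})

test_that("period means respect the half-open window convention", {
  expect_equal(period_mean(c(1, 2, 3), rep(70, 3), c(0, 10)), 70)

  # 30-min series; baseline = last 5 minutes only
  t <- seq(0, 29.9, by = 0.1)
  v <- ifelse(t >= 25, 100, 0)
  expect_equal(period_mean(t, v, c(25, 30)), 100)

  # boundary beat at the window end is excluded, at the start included
  expect_equal(period_mean(c(5, 10), c(1, 99), c(5, 10)), 1)
  expect_error(period_mean(c(1, 2), c(5, 5), c(10, 12)), "\\[10, 12\\)")
})

test_that("change scores reproduce the printed cohort-level deltas", {
  s <- make_summaries(table2_means)
  cs <- compute_change_scores(s)
  expect_equal(cs$sbp_reactivity, 158.72 - 126.88)  # 31.84 mmHg
  expect_equal(cs$hrv_reactivity, 18.22 - 23.65)    # -5.43 ms, vagal withdrawal
  expect_equal(cs$hr_recovery2, 65.34 - 67.15)

  # no stress response at all -> all zeros
  flat <- make_summaries(lapply(table2_means, function(x) table2_means$baseline))
  expect_true(all(unlist(compute_change_scores(flat)[-1]) == 0))

  # adding a constant to every period leaves all deltas unchanged
  shifted <- s
  for (cl in c("sbp", "dbp", "hr", "hrv_rmssd"))
    shifted[[cl]] <- shifted[[cl]] + 17
  expect_equal(compute_change_scores(shifted), cs)

  expect_error(compute_change_scores(s[s$period != "recovery2", ]),
               "recovery2")
})

test_that("cohort-level change scores handle missing periods per contract", {
  s <- rbind(make_summaries(table2_means, id = "a"),
             make_summaries(table2_means[c("baseline", "stress",
                                           "recovery1", "recovery3")],
                            id = "b"),
             make_summaries(table2_means[-1], id = "c"))
  res <- suppressMessages(compute_change_scores_all(s))
  expect_equal(res$excluded$participant_id, "c")  # no baseline: out
  b <- res$scores[res$scores$participant_id == "b", ]
  expect_true(is.na(b$sbp_recovery2))
  expect_false(is.na(b$sbp_recovery1))
})

test_that("the automated outlier screen flags and never mutates", {
  scores <- data.frame(participant_id = sprintf("p%03d", 1:100),
                       sbp_reactivity = rep(30, 100))
  expect_equal(nrow(screen_change_scores(scores)), 0)

  scores$sbp_reactivity <- withr::with_seed(5, rnorm(100, 30, 2))
  scores$sbp_reactivity[17] <- 30 + 10 * 2
  before <- scores
  flags <- screen_change_scores(scores)
  expect_equal(flags$participant_id, "p017")
  expect_identical(scores, before)
})

test_that("beat tables reduce to period summaries with correct units", {
  beats <- data.frame(participant_id = "p1", period = "baseline",
                      beat_index = 1:4, nn_ms = c(990, 1010, 990, 1010),
                      sbp_mmHg = c(120, 122, 118, 120),
                      dbp_mmHg = c(80, 80, 80, 80))
  s <- summarize_periods(beats)
  expect_equal(s$hr, 60000 / 1000)  # mean N-N 1000 ms -> 60 bpm
  expect_equal(s$sbp, 120)
  expect_equal(s$hrv_rmssd, 20)
})
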