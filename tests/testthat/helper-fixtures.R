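# Small in-code fixtures shared across test files.

make_trials <- function(rt_ms, correct = TRUE, id = "p1") {
  data.frame(participant_id = rep(id, length(rt_ms)),
             trial_index = seq_along(rt_ms),
             rt_ms = rt_ms, correct = rep_len(correct, length(rt_ms)))
}

# Period-summary rows for one participant from a named list of
# period -> c(sbp, dbp, hr, hrv).
make_summaries <- function(values, id = "p1") {
  do.call(rbind, lapply(names(values), function(p) {
    v <- values[[p]]
    data.frame(participant_id = id, period = p, sbp = v[1], dbp = v[2],
               hr = v[3], hrv_rmssd = v[4])
  }))
}

# The printed cohort-level period means (SBP, DBP, HR, HRV per period).
table2_means <- list(
  baseline  = c(126.88, 74.61, 67.15, 23.65),
  stress    = c(158.72, 89.57, 76.21, 18.22),
  recovery1 = c(137.87, 80.93, 66.43, 25.62),
  recovery2 = c(136.69, 80.38, 65.34, 26.43),
  recovery3 = c(138.00, 81.33, 65.69, 26.17))

# n x k matrix whose *sample* covariance is exactly the target: whiten the
# centred data with its own sample covariance, then colour with the target.
with_sample_cov <- function(n, target, seed = 1) {
  k <- ncol(target)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * k), n, k)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    W <- Xc %*% solve(chol(cov(Xc)))
    W %*% chol(target) + matrix(rnorm(k), n, k, byrow = TRUE)
  })
}

# Independent brute-force RM-ANOVA sums of squares via explicit loops.
rm_anova_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(mat[, j]) - grand)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(mat[i, ]) - grand)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err +
      (mat[i, j] - mean(mat[i, ]) - mean(mat[, j]) + grand)^2
  }
  ((ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1))))
}
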