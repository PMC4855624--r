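#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor for one-way repeated-measures
#' ANOVA: \eqn{\hat\epsilon = (\sum_i \lambda_i)^2 / ((k-1) \sum_i
#' \lambda_i^2)} over the eigenvalues \eqn{\lambda_i} of the double-centred
#' condition covariance matrix. Bounded in \eqn{[1/(k-1), 1]}; equals 1 when
#' the covariance is compound symmetric (sphericity holds) and 1 exactly when
#' k = 2 (a single contrast cannot violate sphericity).
#'
#' @param mat numeric matrix, participants x conditions (no missing cells),
#'   k = ncol >= 2 conditions.
#' @return epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (anyNA(mat)) stop("no missing cells allowed", call. = FALSE)
  S <- stats::cov(mat)
  # double centring of the covariance matrix
  Sc <- sweep(S, 1, rowMeans(S))
  Sc <- sweep(Sc, 2, colMeans(S))
  Sc <- Sc + mean(S)
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (sum(lam^2) == 0) return(1)  # no contrast variance: sphericity trivial
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Tests the within-subject main effect of condition (here: protocol period)
#' from the two-way subject x condition decomposition:
#' F = MS_condition / MS_(condition x subject), with df (k-1) and
#' (k-1)(n-1). Whenever k > 2 the degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon before the p-value is taken from the F
#' reference, guarding the test against sphericity violations. HRV is
#' conventionally analysed on the log scale (\code{log_transform = TRUE}),
#' matching the long right tail of r-MSSD.
#'
#' @param mat participants x conditions matrix of one outcome; complete cases
#'   only, n >= k.
#' @param outcome label carried into the result (e.g. "sbp").
#' @param log_transform log-transform values before the ANOVA (for HRV)?
#' @return object of class \code{"rm_anova"}: list with \code{F}, \code{df1},
#'   \code{df2} (uncorrected), \code{epsilon}, \code{df1_corr},
#'   \code{df2_corr}, \code{p}, \code{outcome}, \code{n}, \code{k} and
#'   \code{condition_means}.
#' @export
rm_anova <- function(mat, outcome = "outcome", log_transform = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n < k) stop("need at least as many subjects as conditions",
                  call. = FALSE)
  if (anyNA(mat)) stop("no missing cells allowed (complete cases only)",
                       call. = FALSE)
  if (log_transform) {
    if (any(mat <= 0)) stop("log transform requires positive values",
                            call. = FALSE)
    mat <- base::log(mat)
  }

  grand <- mean(mat)
  subj_means <- rowMeans(mat)
  cond_means <- colMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  if (ss_err <= 1e-12 * max(ss_tot, 1)) {
    # degenerate table: no condition-by-subject variability left. With no
    # condition effect either the F statistic is taken as 0 (pure subject
    # effects); otherwise the ratio is undefined.
    if (ss_cond <= 1e-12 * max(ss_tot, 1)) {
      eps <- if (k > 2) gg_epsilon(mat) else 1
      return(structure(list(F = 0, df1 = df1, df2 = df2, epsilon = eps,
                            df1_corr = eps * df1, df2_corr = eps * df2,
                            p = 1, outcome = outcome, n = n, k = k,
                            log_transformed = log_transform,
                            condition_means = cond_means),
                       class = "rm_anova"))
    }
    stop("zero within-cell variability: F undefined", call. = FALSE)
  }
  Fstat <- (ss_cond / df1) / (ss_err / df2)

  eps <- if (k > 2) gg_epsilon(mat) else 1
  df1c <- eps * df1
  df2c <- eps * df2
  p <- stats::pf(Fstat, df1c, df2c, lower.tail = FALSE)

  structure(list(F = Fstat, df1 = df1, df2 = df2, epsilon = eps,
                 df1_corr = df1c, df2_corr = df2c, p = p,
                 outcome = outcome, n = n, k = k,
                 log_transformed = log_transform,
                 condition_means = cond_means),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA, %s%s: F(%.2f, %.2f) = %.2f, p %s\n",
    x$outcome, if (x$log_transformed) " (log)" else "",
    x$df1_corr, x$df2_corr, x$F,
    if (x$p < 0.001) "< .001" else sprintf("= %.3f", x$p)))
  cat(sprintf("  GG epsilon %.3f; n = %d, k = %d\n", x$epsilon, x$n, x$k))
  invisible(x)
}

#' Descriptive pairwise period contrasts
#'
#' Paired t-tests of every condition against the first (baseline) column.
#' Uncorrected and flagged descriptive: these echo the narrative follow-up of
#' a significant main effect, not a formal multiple-comparison procedure.
#'
#' @inheritParams rm_anova
#' @return data.frame with one row per non-baseline condition: mean
#'   difference, t, df, p.
#' @export
period_contrasts <- function(mat, log_transform = FALSE) {
  mat <- as.matrix(mat)
  if (log_transform) mat <- base::log(mat)
  base_col <- mat[, 1]
  out <- lapply(2:ncol(mat), function(j) {
    tt <- stats::t.test(mat[, j], base_col, paired = TRUE)
    data.frame(condition = colnames(mat)[j] %||% paste0("cond", j),
               mean_diff = mean(mat[, j] - base_col),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "note") <- "descriptive; uncorrected paired t-tests vs baseline"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
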