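#' The ex-Gaussian distribution
#'
#' Density, random generation, moments and maximum-likelihood fitting for the
#' ex-Gaussian distribution: the convolution of a Gaussian component with mean
#' \code{mu} and standard deviation \code{sigma} and an independent exponential
#' component with mean \code{tau}. It is the standard model for right-skewed
#' reaction-time (RT) data: \code{mu} and \code{sigma} capture the central
#' tendency and spread of the bulk of responses while \code{tau} carries the
#' long right tail of infrequent slow responses (intraindividual RT
#' variability).
#'
#' The density is
#' \deqn{f(x) = \frac{1}{\tau}\exp\!\left(\frac{\sigma^2}{2\tau^2} -
#'   \frac{x-\mu}{\tau}\right)\Phi\!\left(\frac{x-\mu}{\sigma} -
#'   \frac{\sigma}{\tau}\right)}
#' evaluated in log space (\code{pnorm(..., log.p = TRUE)}) so that small
#' \code{tau} or extreme arguments do not overflow.
#'
#' @param x numeric vector of quantiles (ms).
#' @param mu Gaussian mean (ms).
#' @param sigma Gaussian standard deviation (ms), > 0.
#' @param tau exponential mean (ms), > 0.
#' @param log logical; return log-density?
#' @return \code{dexgauss}: density (per ms) at \code{x}.
#' @examples
#' dexgauss(600, mu = 500, sigma = 50, tau = 100)
#' x <- rexgauss(1000, mu = 500, sigma = 50, tau = 100, seed = 1)
#' exgauss_moments(500, 50, 100)  # mean 600, variance 12500
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  z <- (x - mu) / sigma
  lf <- -base::log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @param n number of draws.
#' @param seed optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return \code{rexgauss}: numeric vector of \code{n} draws (ms).
#' @export
rexgauss <- function(n, mu, sigma, tau, seed = NULL) {
  check_exgauss_params(mu, sigma, tau)
  stopifnot(n >= 1)
  draw <- function() stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @rdname dexgauss
#' @return \code{exgauss_moments}: list with \code{mean} (= mu + tau, ms),
#'   \code{variance} (= sigma^2 + tau^2, ms^2) and unitless \code{skewness}
#'   (= 2 tau^3 / (sigma^2 + tau^2)^{3/2}).
#' @export
exgauss_moments <- function(mu, sigma, tau) {
  check_exgauss_params(mu, sigma, tau)
  v <- sigma^2 + tau^2
  list(mean = mu + tau, variance = v, skewness = 2 * tau^3 / v^(3 / 2))
}

check_exgauss_params <- function(mu, sigma, tau) {
  if (!all(is.finite(mu), is.finite(sigma), is.finite(tau)))
    stop("ex-Gaussian parameters must be finite", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(tau <= 0)) stop("tau must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Maximum-likelihood ex-Gaussian fit
#'
#' Fits (mu, sigma, tau) to a vector of reaction times by maximising the
#' ex-Gaussian log-likelihood. The optimisation runs unconstrained over
#' \code{(mu, log sigma, log tau)} so positivity of \code{sigma} and
#' \code{tau} is structural. Starting values come from the method of moments:
#' \code{tau0 = s * (skew/2)^(1/3)} clipped to \code{[0.05 s, 0.95 s]} (samples
#' with negligible or negative skewness would otherwise yield a degenerate
#' start), \code{sigma0 = sqrt(max(s^2 - tau0^2, (0.05 s)^2))},
#' \code{mu0 = xbar - tau0}.
#'
#' @param rts numeric vector of reaction times (ms); typically the survivors
#'   of [filter_trials()].
#' @param min_n minimum number of observations required (default 20).
#' @param rel_tol relative convergence tolerance passed to the optimiser.
#' @return object of class \code{"exgauss_fit"}: a list with elements
#'   \code{mu}, \code{sigma}, \code{tau} (ms), \code{loglik} (nats),
#'   \code{converged}, \code{n_used}, and \code{diagnostics} (iteration count
#'   and final gradient norm).
#' @examples
#' x <- rexgauss(2000, 2000, 300, 400, seed = 7)
#' fit <- fit_exgauss(x)
#' unlist(fit[c("mu", "sigma", "tau")])
#' @export
fit_exgauss <- function(rts, min_n = 20, rel_tol = 1e-8) {
  rts <- as.numeric(rts)
  if (anyNA(rts) || !all(is.finite(rts)))
    stop("rts must be finite and non-missing", call. = FALSE)
  if (length(rts) < min_n)
    stop(sprintf("need at least %d observations, got %d", min_n, length(rts)),
         call. = FALSE)
  s <- stats::sd(rts)
  if (s == 0) stop("zero-variance input: cannot fit", call. = FALSE)

  xbar <- mean(rts)
  skew <- mean((rts - xbar)^3) / s^3
  tau0 <- s * (max(skew, 0) / 2)^(1 / 3)
  tau0 <- min(max(tau0, 0.05 * s), 0.95 * s)
  sigma0 <- sqrt(max(s^2 - tau0^2, (0.05 * s)^2))
  mu0 <- xbar - tau0

  nll <- function(theta) {
    -sum(dexgauss(rts, theta[1], exp(theta[2]), exp(theta[3]), log = TRUE))
  }
  start <- c(mu0, base::log(sigma0), base::log(tau0))
  opt <- stats::nlminb(start, nll,
                       control = list(rel.tol = rel_tol, iter.max = 500L))
  # central-difference gradient at the optimum, for the diagnostics slot
  g <- vapply(seq_along(opt$par), function(j) {
    h <- 1e-5 * max(1, abs(opt$par[j]))
    e <- replace(numeric(3), j, h)
    (nll(opt$par + e) - nll(opt$par - e)) / (2 * h)
  }, numeric(1))

  structure(list(
    mu = opt$par[1], sigma = exp(opt$par[2]), tau = exp(opt$par[3]),
    loglik = -opt$objective,
    converged = opt$convergence == 0L,
    n_used = length(rts),
    diagnostics = list(iterations = opt$iterations,
                       grad_norm = sqrt(sum(g^2)),
                       start = c(mu = mu0, sigma = sigma0, tau = tau0),
                       loglik_start = -nll(start))
  ), class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat("ex-Gaussian maximum-likelihood fit (n =", x$n_used, ")\n")
  cat(sprintf("  mu = %.2f ms, sigma = %.2f ms, tau = %.2f ms\n",
              x$mu, x$sigma, x$tau))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}
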