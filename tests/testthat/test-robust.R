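test_that("bisquare family has the defining properties", {
  c <- 4.685
  expect_equal(psi_bisquare(0, c), 0)
  expect_true(all(psi_bisquare(c(-10, -c, c, 5, 100), c) == 0))
  # unit derivative at the origin (finite differences)
  h <- 1e-6
  expect_equal((psi_bisquare(h, c) - psi_bisquare(-h, c)) / (2 * h), 1,
               tolerance = 1e-8)
  # odd function; weight = psi(u)/u on the support
  u <- seq(-6, 6, by = 0.37)
  expect_equal(psi_bisquare(u, c), -psi_bisquare(-u, c))
  nz <- u[u != 0]
  expect_equal(wgt_bisquare(nz, c), psi_bisquare(nz, c) / nz)
  # rho is standardised to [0, 1] and increasing in |u|
  expect_equal(rho_bisquare(c(-99, c, 99), c), c(1, 1, 1))
  expect_true(all(diff(rho_bisquare(seq(0, 5, 0.1), c)) >= 0))
  expect_error(psi_bisquare(1, -1), "c must be")
})

test_that("OLS oracle matches closed-form least squares", {
  x <- seq(-3, 3, length.out = 40)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- 2 + 3 * x
  f <- ols_fit(X, y)
  expect_equal(unname(coef(f)), c(2, 3), tolerance = 1e-10)

  y2 <- withr::with_seed(1, y + rnorm(40))
  f2 <- ols_fit(X, y2)
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(X, f2$residuals))), 1e-10)
  # independent normal-equation solve
  beta_ne <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(unname(coef(f2)), unname(drop(beta_ne)), tolerance = 1e-10)
})

test_that("SMDM matches OLS on clean data and resists contamination", {
  set.seed(21)
  n <- 500
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- 2 + 3 * x + rnorm(n)
  fs <- fit_smdm(X, y, smdm_config(seed = 1))
  fo <- ols_fit(X, y)
  expect_true(fs$converged)
  # agreement within 2 Monte-Carlo SEs of the OLS estimate
  expect_true(all(abs(coef(fs) - coef(fo)) < 2 * fo$se))
  expect_true(all(fs$weights >= 0 & fs$weights <= 1))
  expect_true(all(fs$se > 0))

  # independent MM-type implementation agrees on identical data
  fm <- MASS::rlm(X, y, method = "MM", psi = MASS::psi.bisquare,
                  maxit = 100)
  expect_equal(unname(coef(fs)), unname(coef(fm)), tolerance = 1e-3)

  # 20% gross y-outliers: robust slope holds, OLS slope does not
  yc <- y
  yc[1:100] <- 50  # replaced by a +50 cloud unrelated to x
  fsc <- fit_smdm(X, yc, smdm_config(seed = 1))
  foc <- ols_fit(X, yc)
  expect_lt(abs(coef(fsc)[["x"]] - 3), 0.2)
  expect_gt(abs(coef(foc)[["x"]] - 3), 0.2)
  # outlying observations carry low weight
  expect_lt(median(fsc$weights[1:100]), 0.05)
})

test_that("an exact linear law is reproduced with unit weights", {
  x <- seq(1, 60)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- 2 + 3 * x
  f <- fit_smdm(X, y, smdm_config(seed = 2))
  expect_equal(unname(coef(f)), c(2, 3), tolerance = 1e-8)
  expect_true(all(abs(f$weights - 1) < 1e-8))
  expect_equal(f$r2, 1)
})

test_that("R-squared uses raw residuals and matches a brute-force loop", {
  set.seed(4)
  n <- 120
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- 1 + 0.5 * x + rnorm(n)
  f <- fit_smdm(X, y, smdm_config(seed = 3))
  sse <- 0; sst <- 0
  for (i in 1:n) {
    sse <- sse + f$residuals[i]^2
    sst <- sst + (y[i] - mean(y))^2
  }
  expect_equal(f$r2, 1 - sse / sst, tolerance = 1e-12)

  # intercept-only model explains nothing
  f0 <- fit_smdm(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), y,
                 smdm_config(seed = 3))
  expect_equal(f0$r2, 0)
  expect_error(robust_r2(f, rep(5, n)), "zero outcome variance")
})

test_that("both estimators are regression and scale equivariant", {
  set.seed(31)
  n <- 200
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), z = rnorm(n))
  y <- 1 - 2 * X[, 2] + 0.5 * X[, 3] + rnorm(n)
  y[1:20] <- y[1:20] + 30
  cfg <- smdm_config(seed = 6)
  f <- fit_smdm(X, y, cfg)

  a <- c(5, -1, 2)
  f_shift <- fit_smdm(X, y + drop(X %*% a), cfg)
  expect_equal(coef(f_shift), coef(f) + a, tolerance = 1e-6)

  k <- 3.7
  f_scale <- fit_smdm(X, k * y, cfg)
  expect_equal(coef(f_scale), k * coef(f), tolerance = 1e-6)
  expect_equal(f_scale$se, k * f$se, tolerance = 1e-6)
  expect_equal(f_scale$scale, k * f$scale, tolerance = 1e-6)

  o <- ols_fit(X, y)
  o_shift <- ols_fit(X, y + drop(X %*% a))
  expect_equal(coef(o_shift), coef(o) + a, tolerance = 1e-10)
})

test_that("rank-deficient designs are refused by name", {
  X <- cbind(`(Intercept)` = 1, a = 1:30, twice_a = 2 * (1:30))
  expect_error(fit_smdm(X, rnorm(30)), "twice_a")
  expect_error(ols_fit(X, rnorm(30)), "twice_a")
  expect_error(fit_smdm(X[1:6, 1:2], rnorm(6)), "p \\+ 5")
})

test_that("fits are deterministic under a fixed subsampling seed", {
  set.seed(12)
  X <- cbind(`(Intercept)` = 1, x = rnorm(100))
  y <- 1 + 2 * X[, 2] + rt(100, df = 2)
  f1 <- fit_smdm(X, y, smdm_config(seed = 99))
  f2 <- fit_smdm(X, y, smdm_config(seed = 99))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$scale, f2$scale)
})
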