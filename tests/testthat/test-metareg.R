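make_est <- function(y, se = 0.1) {
  mapply(effect_estimate, y, se, SIMPLIFY = FALSE)
}

test_that("noiseless data are fit exactly by both tau2 methods", {
  x <- c(1, 2, 3)
  es <- make_est(0.1 + 0.2 * x)
  for (method in c("reml", "mom")) {
    f <- fit_meta_regression(es, moderator = x, method = method)
    expect_equal(f$slope$log_point, 0.2, tolerance = 1e-8)
    expect_equal(f$intercept$log_point, 0.1, tolerance = 1e-8)
    expect_equal(f$tau_squared_residual, 0)
  }
})

test_that("flat response gives zero slope; errors are informative", {
  es <- make_est(rep(0.3, 4))
  f <- fit_meta_regression(es, moderator = c(1, 2, 3, 4))
  expect_equal(f$slope$log_point, 0, tolerance = 1e-10)

  expect_error(fit_meta_regression(make_est(c(0, 0.1)), moderator = c(1, 2)),
               "at least 3")
  expect_error(fit_meta_regression(make_est(c(0, 0.1, 0.2)),
                                   moderator = c(2, 2, 2)),
               "rank deficient")
})

test_that("moderated_estimate input form is equivalent to vectors", {
  x <- c(1.5, 2.5, 4, 3)
  es <- make_est(c(0.2, 0.35, 0.6, 0.41), se = c(0.1, 0.2, 0.1, 0.15))
  mes <- mapply(moderated_estimate, es, x, SIMPLIFY = FALSE)
  f1 <- fit_meta_regression(es, moderator = x)
  f2 <- fit_meta_regression(mes)
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$tau_squared_residual, f2$tau_squared_residual)
})

test_that("MoM metareg matches the brute-force oracle; REML maximizes the
           restricted likelihood and matches metafor", {
  skip_if_not_installed("metafor")
  set.seed(55)
  for (i in 1:8) {
    k <- sample(5:9, 1)
    x <- runif(k, 2, 5)
    se <- runif(k, 0.05, 0.3)
    y <- 0.05 + 0.14 * x + rnorm(k, 0, 0.12)
    es <- make_est(y, se)

    fm <- fit_meta_regression(es, moderator = x, method = "mom")
    o <- oracle_mom_metareg(y, se, x)
    expect_equal(fm$coefficients, o$beta, tolerance = 1e-10)
    expect_equal(fm$tau_squared_residual, o$tau2, tolerance = 1e-10)
    expect_equal(unname(as.matrix(fm$vcov)), unname(as.matrix(o$vcov)),
                 tolerance = 1e-10)

    fr <- fit_meta_regression(es, moderator = x, method = "reml")
    # REML estimate beats any nearby tau2 on the restricted likelihood
    X <- cbind(1, x)
    nll_hat <- oracle_reml_nll(fr$tau_squared_residual, y, se, X)
    for (cand in c(0.5, 0.9, 1.1, 2) * fr$tau_squared_residual + 1e-6) {
      expect_lte(nll_hat, oracle_reml_nll(cand, y, se, X) + 1e-8)
    }
    mf <- metafor::rma(yi = y, vi = se^2, mods = ~x, method = "REML")
    expect_lt(abs(fr$tau_squared_residual - mf$tau2), 1e-4)
    expect_lt(abs(fr$slope$log_point - as.numeric(mf$beta[2])), 1e-4)
    expect_lt(abs(fr$slope$se - mf$se[2]), 1e-4)
  }
})

test_that("moderator shift moves the intercept, not the slope (MoM)", {
  set.seed(77)
  x <- runif(6, 2, 5)
  es <- make_est(0.1 + 0.15 * x + rnorm(6, 0, 0.1),
                 se = runif(6, 0.05, 0.2))
  f0 <- fit_meta_regression(es, moderator = x, method = "mom")
  fc <- fit_meta_regression(es, moderator = x + 1.3, method = "mom")
  expect_equal(fc$slope$log_point, f0$slope$log_point, tolerance = 1e-10)
  expect_equal(fc$intercept$log_point,
               f0$intercept$log_point - f0$slope$log_point * 1.3,
               tolerance = 1e-10)
})

test_that("with equal SEs and tau2 = 0 the fit reduces to OLS", {
  x <- c(1, 2, 3, 5)
  y <- c(0.11, 0.28, 0.31, 0.52)  # nearly collinear: tau2 truncates to 0
  es <- make_est(y, se = 0.4)
  f <- fit_meta_regression(es, moderator = x, method = "mom")
  expect_equal(f$tau_squared_residual, 0)
  ols <- lm(y ~ x)
  expect_equal(f$coefficients, unname(coef(ols)), tolerance = 1e-10)
})

test_that("r_squared_explained truncates to [0, 100]", {
  expect_equal(r_squared_explained(0.10, 0.04), 60)
  expect_equal(r_squared_explained(0.05, 0.05), 0)
  expect_equal(r_squared_explained(0.05, 0.08), 0)
  expect_equal(r_squared_explained(0, 0), 0)
  expect_error(r_squared_explained(-0.1, 0.05), "non-negative")
})

test_that("predict_at evaluates the line with full covariance", {
  x <- c(1, 2, 3)
  es <- make_est(0.1 + 0.2 * x)
  f <- fit_meta_regression(es, moderator = x)
  expect_equal(predict_at(f, 0)$log_point, f$intercept$log_point)
  expect_equal(predict_at(f, 2)$log_point, 0.5, tolerance = 1e-8)

  # prediction SE is minimized at the weighted mean moderator
  set.seed(9)
  xr <- runif(8, 2, 5)
  esr <- make_est(0.1 + 0.15 * xr + rnorm(8, 0, 0.1),
                  se = runif(8, 0.05, 0.3))
  fr <- fit_meta_regression(esr, moderator = xr)
  w <- 1 / (vapply(esr, `[[`, numeric(1), "se")^2 + fr$tau_squared_residual)
  xbar <- sum(w * xr) / sum(w)
  grid <- seq(min(xr), max(xr), length.out = 101)
  ses <- vapply(grid, function(g) predict_at(fr, g)$se, numeric(1))
  expect_equal(predict_at(fr, xbar)$se, min(c(ses, predict_at(fr, xbar)$se)))
})
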