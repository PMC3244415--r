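test_that("per-mmol/L standardization rescales log effect and SE by 1/Y", {
  e <- effect_estimate(log(0.64), 0.10)
  expect_estimate_equal(standardize_per_mmol(e, 1),
                        log(0.64), 0.10, tol = 1e-12)
  s <- standardize_per_mmol(e, 2)
  expect_equal(exp(s$log_point), 0.8)
  expect_equal(s$se, 0.05)
  expect_identical(s$scale, "per_mmol")
  expect_equal(standardize_per_mmol(effect_estimate(0.2, 0.10), 0.5)$se, 0.2)
  expect_error(standardize_per_mmol(e, 0), "> 0")

  # composition: by Y then Y' equals by Y * Y'
  set.seed(5)
  for (i in 1:10) {
    e <- effect_estimate(rnorm(1), runif(1, 0.01, 0.5))
    y1 <- runif(1, 0.2, 3); y2 <- runif(1, 0.2, 3)
    a <- standardize_per_mmol(standardize_per_mmol(e, y1), y2)
    b <- standardize_per_mmol(e, y1 * y2)
    expect_estimate_equal(a, b$log_point, b$se, tol = 1e-12)
  }
})

test_that("stratum treatment effects follow the intent-to-treat RR", {
  tr <- trial_record("t",
                     carrier_control = trial_cell(80, 1000),
                     carrier_active = trial_cell(40, 1000),
                     noncarrier_control = trial_cell(50, 1000),
                     noncarrier_active = trial_cell(50, 1000),
                     delta_ldl = 1)
  e <- trial_stratum_effect(tr, "carrier")
  expect_equal(exp(e$log_point), 0.5)
  expect_equal(e$se, sqrt(1 / 40 - 1 / 1000 + 1 / 80 - 1 / 1000))

  # same tables standardized over Y = 2
  tr2 <- tr; tr2$delta_ldl <- 2
  e2 <- trial_stratum_effect(tr2, "carrier")
  expect_equal(exp(e2$log_point), sqrt(0.5))
  expect_equal(e2$se, e$se / 2)

  # identical event rates in both arms: per-mmol RR = 1 for any Y
  expect_equal(exp(trial_stratum_effect(tr2, "non_carrier")$log_point), 1)
})

test_that("stratified pooling passes single trials through", {
  tr <- trial_record("t",
                     carrier_control = trial_cell(80, 1000),
                     carrier_active = trial_cell(40, 1000),
                     noncarrier_control = trial_cell(60, 1000),
                     noncarrier_active = trial_cell(45, 1000),
                     delta_ldl = 1.3)
  p <- pool_stratified_trials(list(tr))
  expect_equal(p$carriers$pooled$log_point,
               trial_stratum_effect(tr, "carrier")$log_point)
  expect_equal(p$non_carriers$pooled$log_point,
               trial_stratum_effect(tr, "non_carrier")$log_point)
  expect_equal(p$carriers$k, 1L)
})

test_that("Z comparison reproduces the printed-strata arithmetic", {
  carr <- estimate_from_ci(0.73, 0.66, 0.80)
  nonc <- estimate_from_ci(0.83, 0.76, 0.91)
  cmp <- compare_estimates_z(carr, nonc)
  ci <- confint(cmp$ratio)
  expect_equal(round(ci[["point"]], 2), 0.88)
  expect_equal(round(ci[["lower"]], 2), 0.77)
  expect_equal(round(ci[["upper"]], 2), 1.00)
  expect_equal(cmp$se, sqrt(carr$se^2 + nonc$se^2))
  expect_equal(cmp$z, cmp$log_ratio / cmp$se)
  expect_equal(cmp$p, 2 * pnorm(-abs(cmp$z)))

  # identical strata: ratio 1, z 0, p 1
  same <- compare_estimates_z(carr, carr)
  expect_equal(exp(same$log_ratio), 1)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  expect_equal(exp(cmp$log_ratio) *
                 exp(compare_estimates_z(nonc, carr)$log_ratio), 1)
})

test_that("invert_ratio re-expresses per-increase as per-decrease", {
  slope <- estimate_from_ci(1.15, 1.06, 1.25)
  inv <- invert_ratio(slope)
  ci <- confint(inv)
  expect_equal(round(ci[["point"]], 2), 0.87)
  expect_equal(round(ci[["lower"]], 2), 0.80)
  expect_equal(round(ci[["upper"]], 2), 0.94)
  expect_equal(inv$se, slope$se)

  expect_equal(invert_ratio(effect_estimate(0, 0.1))$log_point, 0)
  back <- invert_ratio(inv)
  expect_estimate_equal(back, slope$log_point, slope$se, tol = 1e-12)
})

test_that("percent_reduction converts pooled RRs to percentages", {
  expect_equal(round(percent_reduction(estimate_from_ci(0.73, 0.66, 0.80))),
               27)
  expect_equal(round(percent_reduction(estimate_from_ci(0.83, 0.76, 0.91))),
               17)
  expect_equal(percent_reduction(effect_estimate(0, 0.1)), 0)
})

test_that("predicted_vs_observed juxtaposes inverted slope and strata", {
  x <- c(2.5, 3.5, 4.5, 3.0, 4.0)
  es <- mapply(effect_estimate, 0.01 + 0.14 * x, rep(0.08, 5),
               SIMPLIFY = FALSE)
  fit <- fit_meta_regression(es, moderator = x)
  tr <- trial_record("t",
                     carrier_control = trial_cell(80, 1000),
                     carrier_active = trial_cell(40, 1000),
                     noncarrier_control = trial_cell(60, 1000),
                     noncarrier_active = trial_cell(45, 1000),
                     delta_ldl = 1.3)
  strata <- pool_stratified_trials(list(tr))
  pvo <- predicted_vs_observed(fit, strata)
  expect_equal(pvo$expected$log_point, -fit$slope$log_point)
  expect_equal(pvo$observed$log_point,
               strata$carriers$pooled$log_point -
                 strata$non_carriers$pooled$log_point)
  expect_equal(pvo$agreement$log_ratio,
               pvo$expected$log_point - pvo$observed$log_point)
})
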