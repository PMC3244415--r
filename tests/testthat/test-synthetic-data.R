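model_default <- vulnerability_model()

test_that("risk follows the log-linear interaction model", {
  m <- vulnerability_model(baseline_risk = 0.05, beta_L = log(1.2),
                           beta_GL = log(1.15), ldl_null = 3.0,
                           ldl_ref = 3.0)
  expect_equal(risk(m, TRUE, 4.0), 0.05 * 1.2 * 1.15)
  # carriers and non-carriers cross exactly at ldl_null
  expect_equal(risk(model_default, TRUE, model_default$ldl_null),
               risk(model_default, FALSE, model_default$ldl_null))
  # no interaction: identical risks at every LDL
  m0 <- vulnerability_model(beta_GL = 0)
  for (ldl in c(2, 3, 4.5)) {
    expect_equal(risk(m0, TRUE, ldl), risk(m0, FALSE, ldl))
  }
  # risks reaching 1 are rejected, not clamped
  expect_error(vulnerability_model(baseline_risk = 0.5, beta_L = log(3)),
               "risk reaches 1")
  expect_error(risk(model_default, TRUE, 40), "risk reaches 1")
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_cohort(model_default, 5000, 3.8, seed = 42)
  b <- simulate_cohort(model_default, 5000, 3.8, seed = 42)
  expect_identical(a, b)
  cc1 <- simulate_case_control(model_default, 800, 900, 3.2, seed = 9)
  cc2 <- simulate_case_control(model_default, 800, 900, 3.2, seed = 9)
  expect_identical(cc1, cc2)
  t1 <- simulate_trial(model_default, 2000, 4.0, 1.0, seed = 7)
  t2 <- simulate_trial(model_default, 2000, 4.0, 1.0, seed = 7)
  expect_identical(t1, t2)
})

test_that("cohort genotypes follow Hardy-Weinberg sampling", {
  q <- model_default$allele_freq
  pc <- 1 - (1 - q)^2
  n <- 20000
  inside <- 0; hwe_pass <- 0
  for (s in 1:50) {
    rec <- simulate_cohort(model_default, n, 3.5, seed = s)
    g <- study_genotypes(rec)
    carrier_frac <- (g$vv + g$vr) / n
    se <- sqrt(pc * (1 - pc) / n)
    inside <- inside + (abs(carrier_frac - pc) <= 3 * se)
    hwe_pass <- hwe_pass + (hwe_chisq(g)$p > 0.001)
  }
  expect_gte(inside / 50, 0.98)
  expect_gte(hwe_pass / 50, 0.98)
})

test_that("null interaction yields stratum RR near 1 at large n", {
  m0 <- vulnerability_model(beta_GL = 0)
  rec <- simulate_cohort(m0, 4e5, 4.2, seed = 31)
  e <- study_effect(rec)
  expect_lt(abs(e$log_point), 3 * e$se)
})

test_that("case-control odds ratio estimates the model RR when rare", {
  m <- vulnerability_model(baseline_risk = 0.01, ldl_null = 3.5)
  true_lrr <- m$beta_G + m$beta_GL * (4.5 - m$ldl_ref)
  lors <- vapply(1:200, function(s) {
    study_effect(simulate_case_control(m, 4000, 4000, 4.5, seed = s))$log_point
  }, numeric(1))
  expect_lt(abs(mean(lors) - true_lrr), 0.02)
  # no interaction at the null-crossing LDL: expected OR 1
  m0 <- vulnerability_model(beta_GL = 0, baseline_risk = 0.01)
  e <- study_effect(simulate_case_control(m0, 5e4, 5e4, m0$ldl_null,
                                          seed = 2))
  expect_lt(abs(e$log_point), 3 * e$se)
})

test_that("trials recover the standardized effects at large n", {
  n <- 2e5
  tr <- simulate_trial(model_default, n, 4.5, 1.0, seed = 13)
  nonc <- trial_stratum_effect(tr, "non_carrier")
  expect_lt(abs(nonc$log_point - (-model_default$beta_L)), 3 * nonc$se)
  carr <- trial_stratum_effect(tr, "carrier")
  cmp <- compare_estimates_z(carr, nonc)
  expect_lt(abs(cmp$log_ratio - (-model_default$beta_GL)), 3 * cmp$se)
  # no LDL effect at all: per-mmol RR near 1 in both strata
  mf <- vulnerability_model(beta_L = 0, beta_GL = 0)
  trf <- simulate_trial(mf, 5e4, 4.0, 1.0, seed = 3)
  for (s in c("carrier", "non_carrier")) {
    e <- trial_stratum_effect(trf, s)
    expect_lt(abs(e$log_point), 3 * e$se)
  }
})

test_that("raising LDL raises events in both strata (monotonicity)", {
  lows <- simulate_cohort(model_default, 2e5, 2.5, seed = 8)
  highs <- simulate_cohort(model_default, 2e5, 4.8, seed = 8)
  for (strata in list(c("argarg", "argtrp"), "trptrp")) {
    low_rate <- sum(lows$strata[strata, "events"]) /
      sum(lows$strata[strata, "total"])
    high_rate <- sum(highs$strata[strata, "events"]) /
      sum(highs$strata[strata, "total"])
    expect_gt(high_rate, low_rate)
  }
})

test_that("the default collection has the paper-like shape", {
  coll <- simulate_paper_like_collection(model_default, seed = 1)
  expect_length(coll$trials, 8)
  eligible <- Filter(is_metareg_eligible, coll$studies)
  expect_length(eligible, 19)
  designs <- table(vapply(coll$studies, `[[`, character(1), "design"))
  expect_equal(designs[["cohort"]], 3)
  expect_equal(designs[["trial_arm"]], 16)
  expect_equal(designs[["case_control"]], 18)
  ctypes <- table(vapply(coll$trials, `[[`, character(1), "control_type"))
  expect_equal(ctypes[["placebo"]], 5)
  expect_equal(ctypes[["less_intensive"]], 3)
  # carriers and non-carriers populated in every trial arm cell
  for (tr in coll$trials) expect_gt(tr$carrier_control$n, 0)
})

test_that("child seeds are stable: adding a study perturbs nothing else", {
  cfg_small <- collection_config(n_case_control = 2, cc_cases = 500,
                                 cc_controls = 500, cohort_n = 2000,
                                 trial_n_per_arm = 800,
                                 cc_ldl = c(2.5, 3.5))
  cfg_big <- collection_config(n_case_control = 3, cc_cases = 500,
                               cc_controls = 500, cohort_n = 2000,
                               trial_n_per_arm = 800,
                               cc_ldl = c(2.5, 3.5, 4.5))
  a <- simulate_paper_like_collection(model_default, cfg_small, seed = 4)
  b <- simulate_paper_like_collection(model_default, cfg_big, seed = 4)
  ids_a <- vapply(a$studies, `[[`, character(1), "id")
  ids_b <- vapply(b$studies, `[[`, character(1), "id")
  for (id in ids_a) {
    expect_identical(a$studies[[match(id, ids_a)]],
                     b$studies[[match(id, ids_b)]])
  }
})

test_that("a collection centered at the null-crossing LDL shows no marginal
           genotype association despite the interaction", {
  covered <- vapply(1:40, function(s) {
    coll <- simulate_paper_like_collection(model_default, seed = s)
    ci <- confint(run_association_meta(coll$studies)$pooled)
    ci[["lower"]] <= 1 && 1 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
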