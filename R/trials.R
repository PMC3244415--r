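#' A genotype-stratified randomized trial record
#'
#' One two-arm trial reported separately among variant-allele carriers and
#' non-carriers: four 2x2 tables (stratum x arm, rows events/at-risk within
#' the arm) plus the between-arm LDL difference achieved during follow-up.
#'
#' @param id Study label.
#' @param carrier_control,carrier_active,noncarrier_control,noncarrier_active
#'   [two_by_two()] tables; by convention the "exposed" row of each table is
#'   unused here — the tables store `events_exposed` = events and
#'   `nonevents_exposed` = non-events of that single arm-stratum cell. Use
#'   [trial_cell()] to build them from events and persons.
#' @param delta_ldl Between-arm difference in average LDL during follow-up
#'   (`Y`, mmol/L, > 0): control minus active.
#' @param control_type `"placebo"` or `"less_intensive"` (trials comparing
#'   two statin intensities are analyzed identically, with the more
#'   intensive arm as "active").
#' @param baseline_ldl Optional mean LDL of the control arm (mmol/L), used
#'   when the arms are recast as cohorts for meta-regression.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(id, carrier_control, carrier_active,
                         noncarrier_control, noncarrier_active,
                         delta_ldl, control_type = c("placebo",
                                                     "less_intensive"),
                         baseline_ldl = NA_real_) {
  control_type <- match.arg(control_type)
  cells <- list(carrier_control = carrier_control,
                carrier_active = carrier_active,
                noncarrier_control = noncarrier_control,
                noncarrier_active = noncarrier_active)
  ok <- vapply(cells, inherits, logical(1), "trial_cell")
  if (!all(ok)) stop("arm-stratum cells must be trial_cell objects",
                     call. = FALSE)
  if (!is.finite(delta_ldl) || delta_ldl <= 0) {
    stop("delta_ldl (Y) must be a positive LDL difference in mmol/L",
         call. = FALSE)
  }
  structure(c(list(id = id), cells,
              list(delta_ldl = delta_ldl, control_type = control_type,
                   baseline_ldl = baseline_ldl)),
            class = "trial_record")
}

#' Events and persons in one arm-stratum cell of a trial
#'
#' @param events Incident events in the cell during follow-up.
#' @param n Persons randomized into the cell (intent to treat).
#' @return An object of class `trial_cell`.
#' @export
trial_cell <- function(events, n) {
  if (events < 0 || n <= 0 || events > n) {
    stop("need 0 <= events <= n with n > 0", call. = FALSE)
  }
  structure(list(events = round(events), n = round(n)), class = "trial_cell")
}

#' Standardize a trial effect per mmol/L of LDL reduction
#'
#' Rescales a log effect and its standard error by `1/Y`, where `Y` is the
#' trial's between-arm LDL difference, putting trials with different degrees
#' of LDL lowering on a common per-mmol/L scale.
#'
#' @param e An [effect_estimate()].
#' @param Y Between-arm LDL difference in mmol/L (> 0).
#' @return An [effect_estimate()] with `scale = "per_mmol"`.
#' @examples
#' standardize_per_mmol(estimate_from_ci(0.64, 0.5, 0.8), Y = 2)  # RR 0.8
#' @export
standardize_per_mmol <- function(e, Y) {
  stopifnot(inherits(e, "effect_estimate"))
  if (!is.finite(Y) || Y <= 0) stop("Y must be > 0 mmol/L", call. = FALSE)
  effect_estimate(e$log_point / Y, e$se / Y, ci_level = e$ci_level,
                  measure_label = e$measure_label, scale = "per_mmol")
}

#' Intent-to-treat per-mmol/L treatment effect in one genotype stratum
#'
#' Builds the active-vs-control 2x2 table for the requested stratum,
#' computes the unadjusted relative risk via [relative_risk()], and
#' standardizes it by the trial's LDL difference via
#' [standardize_per_mmol()].
#'
#' @param t A [trial_record()].
#' @param stratum `"carrier"` or `"non_carrier"`.
#' @param correction Continuity-correction flag passed to
#'   [relative_risk()].
#' @return An [effect_estimate()] on the per-mmol/L scale.
#' @export
trial_stratum_effect <- function(t, stratum = c("carrier", "non_carrier"),
                                 correction = TRUE) {
  stopifnot(inherits(t, "trial_record"))
  stratum <- match.arg(stratum)
  act <- if (stratum == "carrier") t$carrier_active else t$noncarrier_active
  ctl <- if (stratum == "carrier") t$carrier_control else t$noncarrier_control
  tab <- two_by_two(act$events, act$n - act$events,
                    ctl$events, ctl$n - ctl$events)
  standardize_per_mmol(relative_risk(tab, correction = correction),
                       t$delta_ldl)
}

#' Pool standardized trial effects separately by genotype stratum
#'
#' Random-effects ([pool_random_effects()]) pooling of the per-mmol/L
#' intent-to-treat effects, separately among carriers and non-carriers.
#'
#' @param trials List of [trial_record()] objects.
#' @param correction Continuity-correction flag.
#' @return List with `meta_result` components `carriers` and `non_carriers`.
#' @export
pool_stratified_trials <- function(trials, correction = TRUE) {
  if (length(trials) == 0) stop("no trials supplied", call. = FALSE)
  carr <- lapply(trials, trial_stratum_effect, stratum = "carrier",
                 correction = correction)
  nonc <- lapply(trials, trial_stratum_effect, stratum = "non_carrier",
                 correction = correction)
  list(carriers = pool_random_effects(carr),
       non_carriers = pool_random_effects(nonc))
}

#' Z-test comparison of two independent log-scale estimates
#'
#' The difference of log effects with standard error
#' `sqrt(se1^2 + se2^2)`; the exponentiated difference is a ratio of RRs,
#' the package's measure of differential benefit.
#'
#' @param e1,e2 Independent [effect_estimate()]s (e.g. the pooled carrier
#'   and non-carrier per-mmol/L treatment effects).
#' @param ci_level Confidence level of the reported ratio.
#' @return An object of class `comparison_result` with `log_ratio`, `se`,
#'   `z`, two-sided `p`, and `ratio` (an [effect_estimate()] with
#'   `measure_label = "ratio_of_RR"`).
#' @export
compare_estimates_z <- function(e1, e2, ci_level = 0.95) {
  stopifnot(inherits(e1, "effect_estimate"), inherits(e2, "effect_estimate"))
  log_ratio <- e1$log_point - e2$log_point
  se <- sqrt(e1$se^2 + e2$se^2)
  z <- log_ratio / se
  structure(list(
    log_ratio = log_ratio, se = se, z = z,
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    ratio = effect_estimate(log_ratio, se, ci_level = ci_level,
                            measure_label = "ratio_of_RR",
                            scale = e1$scale)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 3, ...) {
  ci <- confint(x$ratio)
  cat(sprintf("ratio of RRs = %.*f (%.0f%% CI %.*f-%.*f), z = %.2f, p = %.3g\n",
              digits, ci["point"], 100 * x$ratio$ci_level,
              digits, ci["lower"], digits, ci["upper"], x$z, x$p))
  invisible(x)
}

#' Invert a ratio estimate (per-increase to per-decrease re-expression)
#'
#' Negates the log effect; the standard error is unchanged and the CI bounds
#' swap and invert. Under the log-linear vulnerability model the effect of a
#' one-unit LDL increase is exactly reciprocal to that of a one-unit
#' decrease, so this re-expresses an excess risk per mmol/L higher LDL as
#' the expected benefit per mmol/L of LDL lowering.
#'
#' @param e An [effect_estimate()].
#' @return The inverted [effect_estimate()].
#' @examples
#' confint(invert_ratio(estimate_from_ci(1.15, 1.06, 1.25)))  # 0.87 (0.80-0.94)
#' @export
invert_ratio <- function(e) {
  stopifnot(inherits(e, "effect_estimate"))
  effect_estimate(-e$log_point, e$se, ci_level = e$ci_level,
                  measure_label = e$measure_label, scale = e$scale)
}

#' Percent risk reduction implied by a ratio estimate
#'
#' `100 (1 - exp(log_point))`: e.g. a pooled RR of 0.73 is a 27% reduction.
#'
#' @param e An [effect_estimate()].
#' @return Percentage (negative for harmful effects).
#' @export
percent_reduction <- function(e) {
  stopifnot(inherits(e, "effect_estimate"))
  100 * (1 - exp(e$log_point))
}

#' Compare predicted and observed differential benefit
#'
#' The meta-regression slope (log ratio of RRs per mmol/L *increase* in LDL)
#' is inverted to the expected benefit ratio per mmol/L *decrease*; the
#' observed benefit ratio is the Z comparison of the pooled carrier vs
#' non-carrier per-mmol/L trial effects. The two ratios — estimated from
#' independent information — are themselves compared by a Z-test.
#'
#' @param fit A `metareg_result` from [fit_meta_regression()] on the
#'   carrier-vs-non-carrier log RRs against study LDL.
#' @param strata List with `meta_result` elements `carriers` and
#'   `non_carriers` from [pool_stratified_trials()].
#' @return A list of class `predicted_observed` with `expected` and
#'   `observed` ([effect_estimate()] ratios per mmol/L decrease),
#'   `observed_comparison` (the stratum `comparison_result`), and
#'   `agreement` (the `comparison_result` of expected vs observed).
#' @export
predicted_vs_observed <- function(fit, strata) {
  stopifnot(inherits(fit, "metareg_result"))
  expected <- invert_ratio(fit$slope)
  obs_cmp <- compare_estimates_z(strata$carriers$pooled,
                                 strata$non_carriers$pooled)
  structure(list(expected = expected,
                 observed = obs_cmp$ratio,
                 observed_comparison = obs_cmp,
                 agreement = compare_estimates_z(expected, obs_cmp$ratio)),
            class = "predicted_observed")
}

#' @export
print.predicted_observed <- function(x, digits = 3, ...) {
  e <- confint(x$expected); o <- confint(x$observed)
  cat(sprintf("expected benefit ratio per mmol/L decrease: %.*f (%.*f-%.*f)\n",
              digits, e["point"], digits, e["lower"], digits, e["upper"]))
  cat(sprintf("observed benefit ratio per mmol/L decrease: %.*f (%.*f-%.*f)\n",
              digits, o["point"], digits, o["lower"], digits, o["upper"]))
  cat(sprintf("agreement z = %.2f, p = %.3g\n",
              x$agreement$z, x$agreement$p))
  invisible(x)
}
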