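#' Write a study collection to the pipeline CSV schema
#'
#' One row per study-stratum(-arm). Columns: `study_id`, `design`
#' (`cohort`/`case_control`/`trial`), `arm` (`na`/`control`/`active`),
#' `stratum` (`argarg`/`argtrp`/`trptrp`), `events`, `total`, `mean_ldl`,
#' `delta_ldl` (trial rows only), `control_type` (trial rows only). For
#' case-control rows `events` holds prevalent cases and `total` cases plus
#' controls.
#'
#' @param collection List with `studies` and `trials`, as produced by
#'   [simulate_paper_like_collection()] or [read_studies()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(collection, path) {
  utils::write.csv(.collection_to_df(collection), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

.collection_to_df <- function(collection) {
  rows <- list()
  trial_ids <- vapply(collection$trials, `[[`, character(1), "id")
  for (s in collection$studies) {
    if (s$design == "trial_arm" && s$trial_id %in% trial_ids) next
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = s$id, design = s$design, arm = s$arm,
      stratum = s$strata$stratum, events = s$strata$events,
      total = s$strata$total, mean_ldl = s$mean_ldl,
      delta_ldl = NA_real_, control_type = s$control_type)
  }
  for (tr in collection$trials) {
    for (arm in names(tr$arms)) {
      a <- tr$arms[[arm]]
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = tr$id, design = "trial", arm = arm,
        stratum = a$strata$stratum, events = a$strata$events,
        total = a$strata$total, mean_ldl = a$mean_ldl,
        delta_ldl = tr$delta_ldl, control_type = tr$control_type)
    }
  }
  do.call(rbind, rows)
}

#' Read a study collection from the pipeline CSV schema
#'
#' Inverse of [write_studies()]. Malformed rows are reported with 1-based
#' data row numbers and the offending columns.
#'
#' @param path Input CSV path.
#' @return A list with `studies` (list of [study_record()], trial arms
#'   included as separate prospective cohorts) and `trials` (list of
#'   [trial_record()]).
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "design", "arm", "stratum", "events", "total",
            "mean_ldl", "delta_ldl")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("CSV schema violation: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"control_type" %in% names(df)) df$control_type <- NA_character_
  rowno <- seq_len(nrow(df))
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(sprintf("CSV parse error in row(s) %s: %s",
                   paste(rowno[which(cond)], collapse = ", "), what),
           call. = FALSE)
    }
  }
  bad(!df$design %in% c("cohort", "case_control", "trial"),
      "unknown design")
  bad(!df$stratum %in% c("argarg", "argtrp", "trptrp"), "unknown stratum")
  bad(is.na(df$events) | df$events < 0, "negative or missing events")
  bad(is.na(df$total) | df$total < 0, "negative or missing total")
  bad(df$events > df$total, "events exceed total")
  bad(df$design == "trial" &
        (is.na(df$delta_ldl) | df$delta_ldl <= 0),
      "trial row missing a positive delta_ldl (Y)")
  bad(df$design == "trial" & !df$arm %in% c("control", "active"),
      "trial row with arm other than control/active")

  studies <- list()
  trials <- list()
  for (sid in unique(df$study_id)) {
    part <- df[df$study_id == sid, ]
    design <- part$design[1]
    if (design != "trial") {
      studies[[length(studies) + 1L]] <- study_record(
        sid, design,
        data.frame(stratum = part$stratum, events = part$events,
                   total = part$total),
        mean_ldl = part$mean_ldl[1])
      next
    }
    ct <- part$control_type[1]
    if (is.na(ct) || !nzchar(ct)) ct <- "placebo"
    arms <- list()
    for (arm in c("control", "active")) {
      ap <- part[part$arm == arm, ]
      if (nrow(ap) == 0) {
        stop(sprintf("trial %s is missing its %s arm", sid, arm),
             call. = FALSE)
      }
      arms[[arm]] <- study_record(
        paste(sid, arm, sep = "_"), "trial_arm",
        data.frame(stratum = ap$stratum, events = ap$events,
                   total = ap$total),
        mean_ldl = ap$mean_ldl[1], arm = arm, control_type = ct,
        trial_id = sid)
      studies[[length(studies) + 1L]] <- arms[[arm]]
    }
    cell <- function(record, strata) {
      s <- record$strata[strata, ]
      trial_cell(sum(s$events), sum(s$total))
    }
    carr <- c("argarg", "argtrp")
    tr <- trial_record(
      sid,
      carrier_control = cell(arms$control, carr),
      carrier_active = cell(arms$active, carr),
      noncarrier_control = cell(arms$control, "trptrp"),
      noncarrier_active = cell(arms$active, "trptrp"),
      delta_ldl = part$delta_ldl[1], control_type = ct,
      baseline_ldl = arms$control$mean_ldl)
    tr$arms <- arms
    trials[[length(trials) + 1L]] <- tr
  }
  list(studies = studies, trials = trials)
}

#' Random-effects meta-analysis of the genotype-disease association
#'
#' Per-study unadjusted effects (RR for prospective designs, OR for
#' case-control) pooled by DerSimonian-Laird random effects.
#'
#' @param studies List of [study_record()]s.
#' @param stratification Genotype contrast; see [study_table()].
#' @param correction Continuity-correction flag.
#' @return A `meta_result` (see [pool_random_effects()]) with a
#'   `study_ids` attribute.
#' @export
run_association_meta <- function(studies,
                                 stratification = c("carrier", "homozygous",
                                                    "heterozygous"),
                                 correction = TRUE) {
  stratification <- match.arg(stratification)
  if (length(studies) == 0) stop("no eligible studies", call. = FALSE)
  es <- lapply(studies, study_effect, stratification = stratification,
               correction = correction)
  out <- pool_random_effects(es)
  attr(out, "study_ids") <- vapply(studies, `[[`, character(1), "id")
  out
}

#' LDL meta-regression of the genotype-disease association
#'
#' Fits [fit_meta_regression()] of the per-study carrier log RR on study
#' mean LDL over the meta-regression-eligible records (prospective units
#' with known LDL).
#'
#' @inheritParams run_association_meta
#' @param method `tau2` method, `"reml"` or `"mom"`.
#' @return A `metareg_result` with a `study_ids` attribute.
#' @export
run_metareg <- function(studies,
                        stratification = c("carrier", "homozygous",
                                           "heterozygous"),
                        method = c("reml", "mom"), correction = TRUE) {
  stratification <- match.arg(stratification)
  method <- match.arg(method)
  eligible <- Filter(is_metareg_eligible, studies)
  if (length(eligible) < 3) {
    stop("fewer than 3 meta-regression-eligible studies", call. = FALSE)
  }
  es <- lapply(eligible, study_effect, stratification = stratification,
               correction = correction)
  x <- vapply(eligible, `[[`, numeric(1), "mean_ldl")
  out <- fit_meta_regression(es, moderator = x, method = method)
  attr(out, "study_ids") <- vapply(eligible, `[[`, character(1), "id")
  out
}

# The named design filters of the sensitivity table.
.sensitivity_subsets <- function() {
  list(
    all = function(s) is_metareg_eligible(s),
    cohorts = function(s) s$design == "cohort" && is_metareg_eligible(s),
    placebo_arms = function(s) s$design == "trial_arm" &&
      s$arm == "control" && identical(s$control_type, "placebo"),
    cohorts_placebo_arms = function(s)
      (s$design == "cohort" && is_metareg_eligible(s)) ||
      (s$design == "trial_arm" && s$arm == "control" &&
         identical(s$control_type, "placebo")),
    control_arms = function(s) s$design == "trial_arm" &&
      s$arm == "control",
    cohorts_control_arms = function(s)
      (s$design == "cohort" && is_metareg_eligible(s)) ||
      (s$design == "trial_arm" && s$arm == "control"),
    cohorts_active_arms = function(s)
      (s$design == "cohort" && is_metareg_eligible(s)) ||
      (s$design == "trial_arm" && s$arm == "active"))
}

#' Sensitivity analysis of the effect modification across design subsets
#'
#' Refits the LDL meta-regression on each named subset of the eligible
#' records (all units; cohorts only; placebo arms; cohorts + placebo arms;
#' control arms; cohorts + control arms; cohorts + active arms) and reports
#' the per-mmol/L-*decrease* benefit ratio (the inverted slope) for each.
#' Subsets with fewer than 3 studies are flagged not-estimable rather than
#' erroring.
#'
#' @inheritParams run_metareg
#' @param subsets Named list of predicate functions over [study_record()]s;
#'   defaults to the design-based subsets above.
#' @return Named list; each element has `k`, `study_ids`, and either
#'   `ratio_per_mmol_decrease` (an [effect_estimate()]) plus the underlying
#'   `fit`, or `estimable = FALSE`.
#' @export
run_sensitivity <- function(studies, subsets = .sensitivity_subsets(),
                            method = c("reml", "mom"), correction = TRUE) {
  method <- match.arg(method)
  out <- list()
  for (name in names(subsets)) {
    keep <- Filter(subsets[[name]], studies)
    ids <- vapply(keep, `[[`, character(1), "id")
    if (length(keep) < 3) {
      out[[name]] <- list(k = length(keep), study_ids = ids,
                          estimable = FALSE)
      next
    }
    fit <- run_metareg(keep, method = method, correction = correction)
    out[[name]] <- list(k = fit$k, study_ids = ids, estimable = TRUE,
                        ratio_per_mmol_decrease = invert_ratio(fit$slope),
                        fit = fit)
  }
  out
}

#' Run the full vulnerability analysis chain
#'
#' Association meta-analysis over all studies; LDL meta-regression over the
#' eligible prospective units; per-mmol/L standardized, genotype-stratified
#' pooling of the trials; the predicted-vs-observed benefit comparison; and
#' the design-subset sensitivity table.
#'
#' @param collection List with `studies` and `trials` (from
#'   [read_studies()] or [simulate_paper_like_collection()]).
#' @param tau2_method Meta-regression `tau2` method (`"reml"` or `"mom"`).
#' @param correction Continuity-correction flag used throughout.
#' @param seed Seed recorded in the provenance block (the analysis itself
#'   is deterministic).
#' @return An object of class `analysis_report`.
#' @export
run_full_analysis <- function(collection, tau2_method = c("reml", "mom"),
                              correction = TRUE, seed = NA_integer_) {
  tau2_method <- match.arg(tau2_method)
  studies <- collection$studies
  trials <- collection$trials
  association <- run_association_meta(studies, correction = correction)
  metareg <- run_metareg(studies, method = tau2_method,
                         correction = correction)
  strata <- pool_stratified_trials(trials, correction = correction)
  pvo <- predicted_vs_observed(metareg, strata)
  sens <- run_sensitivity(studies, method = tau2_method,
                          correction = correction)
  structure(list(
    association = association,
    metareg = metareg,
    trial_strata = strata,
    expected_benefit = pvo$expected,
    observed_benefit = pvo$observed_comparison,
    predicted_observed = pvo,
    sensitivity = sens,
    provenance = list(
      n_studies = length(studies), n_trials = length(trials),
      seed = seed, tau2_method = tau2_method, correction = correction,
      input_digest = .collection_digest(collection))),
    class = "analysis_report")
}

.collection_digest <- function(collection) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_studies(collection, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, digits = 3, ...) {
  cat("== Genotype-disease association (all studies) ==\n")
  print(x$association, digits = digits)
  cat("\n== LDL meta-regression (prospective units) ==\n")
  print(x$metareg, digits = digits)
  cat("\n== Stratified statin-trial benefit (per mmol/L) ==\n")
  cat("carriers:     "); print(x$trial_strata$carriers$pooled, digits)
  cat("non-carriers: "); print(x$trial_strata$non_carriers$pooled, digits)
  cat("\n== Predicted vs observed differential benefit ==\n")
  print(x$predicted_observed, digits = digits)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic (byte-identical for identical inputs and settings) flat
#' JSON rendering of the headline numbers.
#'
#' @param report An `analysis_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  ci3 <- function(e) {
    ci <- confint(e)
    list(point = ci[["point"]], lower = ci[["lower"]],
         upper = ci[["upper"]], log_point = e$log_point, se = e$se)
  }
  sens <- lapply(report$sensitivity, function(s) {
    if (!isTRUE(s$estimable)) return(list(k = s$k, estimable = FALSE))
    c(list(k = s$k, estimable = TRUE),
      ci3(s$ratio_per_mmol_decrease))
  })
  obj <- list(
    association = c(ci3(report$association$pooled),
                    list(k = report$association$k,
                         Q = report$association$Q,
                         i_squared = report$association$i_squared,
                         tau_squared = report$association$tau_squared)),
    metareg = list(
      slope = ci3(report$metareg$slope),
      intercept = ci3(report$metareg$intercept),
      tau_squared_residual = report$metareg$tau_squared_residual,
      tau_squared_null = report$metareg$tau_squared_null,
      r_squared = report$metareg$r_squared,
      k = report$metareg$k, method = report$metareg$method),
    trial_strata = list(
      carriers = ci3(report$trial_strata$carriers$pooled),
      non_carriers = ci3(report$trial_strata$non_carriers$pooled)),
    expected_benefit = ci3(report$expected_benefit),
    observed_benefit = c(ci3(report$observed_benefit$ratio),
                         list(z = report$observed_benefit$z,
                              p = report$observed_benefit$p)),
    agreement = list(z = report$predicted_observed$agreement$z,
                     p = report$predicted_observed$agreement$p),
    sensitivity = sens,
    provenance = report$provenance)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Fixed-width text forest table of a pooled analysis
#'
#' @param meta A `meta_result`.
#' @param estimates The list of [effect_estimate()]s that was pooled.
#' @param labels Study labels (defaults to the `study_ids` attribute of
#'   `meta`, else sequential numbers).
#' @return Character vector of table lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print Cat the table to the console?
#' @export
forest_table <- function(meta, estimates,
                         labels = attr(meta, "study_ids"), print = TRUE) {
  stopifnot(inherits(meta, "meta_result"))
  if (is.null(labels)) labels <- sprintf("study_%02d", seq_along(estimates))
  wtot <- sum(meta$weights)
  lines <- sprintf("%-18s %8s %8s %8s %7s", "study", "est", "lo", "hi",
                   "wt(%)")
  for (i in seq_along(estimates)) {
    ci <- confint(estimates[[i]])
    lines <- c(lines, sprintf("%-18s %8.3f %8.3f %8.3f %7.2f",
                              substr(labels[i], 1, 18), ci["point"],
                              ci["lower"], ci["upper"],
                              100 * meta$weights[i] / wtot))
  }
  ci <- confint(meta$pooled)
  lines <- c(lines, sprintf("%-18s %8.3f %8.3f %8.3f %7s", "POOLED",
                            ci["point"], ci["lower"], ci["upper"], ""))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
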