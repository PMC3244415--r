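#' A study-level record with genotype-stratified counts
#'
#' One analysis unit: an epidemiologic cohort, a case-control study, or a
#' single treatment-allocation arm of a randomized trial (each arm is
#' treated as a separate prospective cohort). Counts are held per genotype
#' stratum so that both carrier-level and genotype-level contrasts can be
#' formed.
#'
#' @param id Study label.
#' @param design `"cohort"`, `"case_control"`, or `"trial_arm"`.
#' @param strata A data frame with columns `stratum` (values `"argarg"`,
#'   `"argtrp"`, `"trptrp"`), `events` and `total`. For prospective designs
#'   `events` is incident events and `total` persons at risk; for
#'   case-control, `events` is prevalent cases and `total` is cases plus
#'   controls in the stratum.
#' @param mean_ldl Study mean LDL in mmol/L (`NA` when not reported, e.g.
#'   typical case-control studies); required for meta-regression
#'   eligibility.
#' @param arm `"na"`, `"control"`, or `"active"` (trial arms only).
#' @param control_type `"placebo"` or `"less_intensive"` for trial arms.
#' @param trial_id Parent trial label for trial arms.
#' @return An object of class `study_record`.
#' @export
study_record <- function(id, design = c("cohort", "case_control",
                                        "trial_arm"),
                         strata, mean_ldl = NA_real_,
                         arm = c("na", "control", "active"),
                         control_type = NA_character_,
                         trial_id = NA_character_) {
  design <- match.arg(design)
  arm <- match.arg(arm)
  need <- c("stratum", "events", "total")
  if (!is.data.frame(strata) || !all(need %in% names(strata))) {
    stop("strata must be a data frame with stratum/events/total columns",
         call. = FALSE)
  }
  if (!setequal(strata$stratum, c("argarg", "argtrp", "trptrp"))) {
    stop("strata must contain exactly argarg, argtrp, trptrp rows",
         call. = FALSE)
  }
  if (any(strata$events < 0) || any(strata$total < 0) ||
      any(strata$events > strata$total)) {
    stop("need 0 <= events <= total in every stratum", call. = FALSE)
  }
  if (design == "trial_arm" && arm == "na") {
    stop("trial arms must declare arm = control or active", call. = FALSE)
  }
  rownames(strata) <- strata$stratum
  structure(list(id = id, design = design, strata = strata,
                 mean_ldl = mean_ldl, arm = arm,
                 control_type = control_type, trial_id = trial_id),
            class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("study %s [%s%s], mean LDL %s mmol/L\n", x$id, x$design,
              if (x$arm != "na") paste0(", ", x$arm, " arm") else "",
              ifelse(is.na(x$mean_ldl), "NA", format(x$mean_ldl))))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

# Counts for a genotype contrast: exposed stratum set vs referent set.
.contrast_counts <- function(record, exposed, referent) {
  s <- record$strata
  ev_e <- sum(s[exposed, "events"]); tot_e <- sum(s[exposed, "total"])
  ev_u <- sum(s[referent, "events"]); tot_u <- sum(s[referent, "total"])
  two_by_two(ev_e, tot_e - ev_e, ev_u, tot_u - ev_u)
}

#' 2x2 genotype-contrast table from a study record
#'
#' For prospective designs the rows are events/at-risk; for case-control the
#' rows are cases/controls of each genotype group, so the appropriate
#' measure is the odds ratio.
#'
#' @param record A [study_record()].
#' @param stratification `"carrier"` (Arg/Arg + Arg/Trp vs Trp/Trp),
#'   `"homozygous"` (Arg/Arg vs Trp/Trp), or `"heterozygous"` (Arg/Trp vs
#'   Trp/Trp).
#' @return A [two_by_two()].
#' @export
study_table <- function(record,
                        stratification = c("carrier", "homozygous",
                                           "heterozygous")) {
  stopifnot(inherits(record, "study_record"))
  stratification <- match.arg(stratification)
  exposed <- switch(stratification,
                    carrier = c("argarg", "argtrp"),
                    homozygous = "argarg",
                    heterozygous = "argtrp")
  .contrast_counts(record, exposed, "trptrp")
}

#' Unadjusted genotype-association effect for a study
#'
#' Relative risk for prospective designs (cohorts and trial arms), odds
#' ratio for case-control studies (as an approximation of the RR, entering
#' downstream pooling on the same log scale).
#'
#' @inheritParams study_table
#' @param correction Continuity-correction flag (see [relative_risk()]).
#' @param ci_level Confidence level.
#' @return An [effect_estimate()].
#' @export
study_effect <- function(record,
                         stratification = c("carrier", "homozygous",
                                            "heterozygous"),
                         correction = TRUE, ci_level = 0.95) {
  tab <- study_table(record, stratification)
  if (record$design == "case_control") {
    odds_ratio(tab, correction = correction, ci_level = ci_level)
  } else {
    relative_risk(tab, correction = correction, ci_level = ci_level)
  }
}

#' Genotype counts of a study record
#'
#' @param record A [study_record()].
#' @return A [genotype_counts()] built from the stratum totals.
#' @export
study_genotypes <- function(record) {
  stopifnot(inherits(record, "study_record"))
  s <- record$strata
  genotype_counts(s["argarg", "total"], s["argtrp", "total"],
                  s["trptrp", "total"])
}

#' Is a study eligible for LDL meta-regression?
#'
#' Prospective units (cohorts and trial arms, which are analyzed as separate
#' cohorts) with a known mean LDL.
#'
#' @param record A [study_record()].
#' @return Logical.
#' @export
is_metareg_eligible <- function(record) {
  record$design %in% c("cohort", "trial_arm") && is.finite(record$mean_ldl)
}
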