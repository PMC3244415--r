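#' Log-linear genotype-by-LDL vulnerability risk model
#'
#' The generative model behind every simulator in the package. Event risk is
#' log-linear in LDL, with the variant genotype scaling the per-mmol/L
#' effect:
#'
#' `risk = baseline_risk * exp(beta_L (L - ldl_ref) +
#'   carrier * (beta_G + beta_GL (L - ldl_ref)))`
#'
#' where `beta_G = -beta_GL (ldl_null - ldl_ref)`, so that carriers and
#' non-carriers have identical risk exactly at `ldl_null` — at higher LDL
#' the variant is positively associated with events, at lower LDL
#' inversely, and a collection of studies centered near `ldl_null` shows no
#' marginal genotype association despite the interaction.
#'
#' @param baseline_risk Event probability of a non-carrier at `ldl_ref`.
#' @param beta_L Log RR per mmol/L LDL among non-carriers.
#' @param beta_GL Interaction: log ratio of RRs per mmol/L (carrier minus
#'   non-carrier LDL slope).
#' @param ldl_null LDL level (mmol/L) at which the carrier vs non-carrier
#'   RR equals 1.
#' @param allele_freq Variant allele frequency in (0, 1); genotypes are in
#'   Hardy-Weinberg proportions.
#' @param ldl_ref Reference LDL (mmol/L) at which `baseline_risk` applies.
#' @param ldl_range The LDL interval over which the model must produce
#'   valid probabilities; parameterizations whose risk reaches 1 anywhere
#'   on it are rejected.
#' @return An object of class `vulnerability_model`.
#' @export
vulnerability_model <- function(baseline_risk = 0.05,
                                beta_L = log(1.25),
                                beta_GL = log(1.15),
                                ldl_null = 3.5,
                                allele_freq = 0.37,
                                ldl_ref = 3.0,
                                ldl_range = c(2.0, 5.0)) {
  if (baseline_risk <= 0 || baseline_risk >= 1) {
    stop("baseline_risk must lie in (0, 1)", call. = FALSE)
  }
  if (allele_freq <= 0 || allele_freq >= 1) {
    stop("allele_freq must lie in (0, 1)", call. = FALSE)
  }
  m <- structure(list(baseline_risk = baseline_risk, beta_L = beta_L,
                      beta_GL = beta_GL, ldl_null = ldl_null,
                      allele_freq = allele_freq, ldl_ref = ldl_ref,
                      beta_G = -beta_GL * (ldl_null - ldl_ref),
                      ldl_range = sort(ldl_range)),
                 class = "vulnerability_model")
  # risk is monotone in LDL for each stratum, so the endpoints bound it
  for (carrier in c(FALSE, TRUE)) {
    risk(m, carrier, m$ldl_range)  # errors if any risk >= 1
  }
  m
}

#' @export
print.vulnerability_model <- function(x, ...) {
  cat(sprintf(paste0(
    "vulnerability model: baseline risk %.3g at LDL %.2f mmol/L\n",
    "  RR per mmol/L: %.3f (non-carriers), %.3f (carriers); null crossing at %.2f\n",
    "  variant allele frequency %.2f (carrier fraction %.3f)\n"),
    x$baseline_risk, x$ldl_ref, exp(x$beta_L), exp(x$beta_L + x$beta_GL),
    x$ldl_null, x$allele_freq, 1 - (1 - x$allele_freq)^2))
  invisible(x)
}

#' Event risk under the vulnerability model
#'
#' @param model A [vulnerability_model()].
#' @param carrier Logical: variant-allele carrier?
#' @param ldl LDL level(s) in mmol/L.
#' @return Event probability (vectorized over `ldl`); risks reaching 1 are
#'   a parameterization error, never clamped.
#' @export
risk <- function(model, carrier, ldl) {
  stopifnot(inherits(model, "vulnerability_model"))
  d <- ldl - model$ldl_ref
  lp <- model$beta_L * d +
    as.numeric(carrier) * (model$beta_G + model$beta_GL * d)
  r <- model$baseline_risk * exp(lp)
  if (any(r >= 1)) {
    stop("model risk reaches 1 within the requested LDL range; ",
         "invalid parameterization", call. = FALSE)
  }
  r
}

# Hardy-Weinberg genotype probabilities (argarg, argtrp, trptrp).
.hwe_probs <- function(q) c(q^2, 2 * q * (1 - q), (1 - q)^2)

# Stable, platform-independent child seed: polynomial hash of the study id
# folded with the master seed, kept below 2^31 - 1.
.child_seed <- function(master, id) {
  bytes <- utf8ToInt(as.character(id))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (master %% 2147483647) * 48271) %% 2147483647)
}

#' Simulate a prospective cohort under the vulnerability model
#'
#' Genotypes are drawn in Hardy-Weinberg proportions at the model's allele
#' frequency; incident events are drawn binomially per genotype stratum at
#' the model risk for the study's mean LDL. Deterministic for a fixed seed.
#'
#' @param model A [vulnerability_model()].
#' @param n Cohort size.
#' @param mean_ldl Study mean LDL (mmol/L).
#' @param seed Integer seed.
#' @param id Study label.
#' @return A [study_record()] with `design = "cohort"`.
#' @export
simulate_cohort <- function(model, n, mean_ldl, seed, id = "cohort") {
  stopifnot(inherits(model, "vulnerability_model"), n > 0)
  set.seed(seed)
  g <- drop(stats::rmultinom(1, n, .hwe_probs(model$allele_freq)))
  risks <- c(risk(model, TRUE, mean_ldl), risk(model, TRUE, mean_ldl),
             risk(model, FALSE, mean_ldl))
  events <- stats::rbinom(3, g, risks)
  study_record(id, "cohort",
               data.frame(stratum = c("argarg", "argtrp", "trptrp"),
                          events = events, total = g),
               mean_ldl = mean_ldl)
}

#' Simulate a case-control study under the vulnerability model
#'
#' Genotype frequencies among prevalent cases and controls follow from
#' Bayes inversion of the population genotype mixture against the model
#' risks at the study's LDL level: `P(g | case)` is proportional to the
#' Hardy-Weinberg prior times the genotype risk, `P(g | control)` to the
#' prior times one minus the risk. In the rare-disease regime the resulting
#' odds ratio estimates the model relative risk.
#'
#' The returned record carries `mean_ldl = NA`: case-control studies enter
#' the association meta-analysis but (as in typical published collections)
#' do not report a usable mean LDL for meta-regression.
#'
#' @param model A [vulnerability_model()].
#' @param n_cases,n_controls Numbers of prevalent cases and of controls.
#' @param mean_ldl LDL level (mmol/L) of the source population.
#' @param seed Integer seed.
#' @param id Study label.
#' @return A [study_record()] with `design = "case_control"`.
#' @export
simulate_case_control <- function(model, n_cases, n_controls, mean_ldl,
                                  seed, id = "case_control") {
  stopifnot(inherits(model, "vulnerability_model"),
            n_cases > 0, n_controls > 0)
  set.seed(seed)
  prior <- .hwe_probs(model$allele_freq)
  risks <- c(risk(model, TRUE, mean_ldl), risk(model, TRUE, mean_ldl),
             risk(model, FALSE, mean_ldl))
  p_case <- prior * risks / sum(prior * risks)
  p_ctrl <- prior * (1 - risks) / sum(prior * (1 - risks))
  cases <- drop(stats::rmultinom(1, n_cases, p_case))
  controls <- drop(stats::rmultinom(1, n_controls, p_ctrl))
  study_record(id, "case_control",
               data.frame(stratum = c("argarg", "argtrp", "trptrp"),
                          events = cases, total = cases + controls),
               mean_ldl = NA_real_)
}

#' Simulate a genotype-stratified two-arm trial
#'
#' Both arms draw genotypes from the same Hardy-Weinberg mixture (valid
#' randomization); the control arm experiences event risks at
#' `baseline_ldl` and the active arm at `baseline_ldl - delta_ldl`,
#' emulating LDL lowering. The record carries `Y = delta_ldl` for
#' per-mmol/L standardization, and the two arms are also returned as
#' `trial_arm` [study_record()]s (each arm a separate prospective cohort)
#' for the association and meta-regression analyses.
#'
#' @param model A [vulnerability_model()].
#' @param n_per_arm Persons randomized to each arm.
#' @param baseline_ldl Control-arm mean LDL (mmol/L).
#' @param delta_ldl Between-arm LDL difference `Y` (mmol/L, > 0).
#' @param seed Integer seed.
#' @param id Trial label.
#' @param control_type `"placebo"` or `"less_intensive"`.
#' @return A [trial_record()] whose `arms` field holds the two
#'   [study_record()]s.
#' @export
simulate_trial <- function(model, n_per_arm, baseline_ldl, delta_ldl, seed,
                           id = "trial",
                           control_type = c("placebo", "less_intensive")) {
  stopifnot(inherits(model, "vulnerability_model"),
            n_per_arm > 0, delta_ldl > 0)
  control_type <- match.arg(control_type)
  set.seed(seed)
  arms <- list()
  ldl <- c(control = baseline_ldl, active = baseline_ldl - delta_ldl)
  for (arm in names(ldl)) {
    g <- drop(stats::rmultinom(1, n_per_arm, .hwe_probs(model$allele_freq)))
    risks <- c(risk(model, TRUE, ldl[[arm]]), risk(model, TRUE, ldl[[arm]]),
               risk(model, FALSE, ldl[[arm]]))
    events <- stats::rbinom(3, g, risks)
    arms[[arm]] <- study_record(
      paste(id, arm, sep = "_"), "trial_arm",
      data.frame(stratum = c("argarg", "argtrp", "trptrp"),
                 events = events, total = g),
      mean_ldl = ldl[[arm]], arm = arm, control_type = control_type,
      trial_id = id)
  }
  cell <- function(record, strata) {
    s <- record$strata[strata, ]
    trial_cell(sum(s$events), sum(s$total))
  }
  carr <- c("argarg", "argtrp")
  tr <- trial_record(
    id,
    carrier_control = cell(arms$control, carr),
    carrier_active = cell(arms$active, carr),
    noncarrier_control = cell(arms$control, "trptrp"),
    noncarrier_active = cell(arms$active, "trptrp"),
    delta_ldl = delta_ldl, control_type = control_type,
    baseline_ldl = baseline_ldl)
  tr$arms <- arms
  tr
}

#' Default configuration for a paper-shaped study collection
#'
#' The structural template the simulator fills in: 3 large epidemiologic
#' cohorts, 8 two-arm trials (5 placebo-controlled, 3 intensity
#' comparisons; all 16 arms double as prospective cohorts, giving 19
#' meta-regression-eligible units), and 18 case-control studies without
#' reported LDL. Study sizes echo a collection of ~145,000 participants.
#'
#' @param n_cohorts,cohort_n Number and size of pure cohorts.
#' @param cohort_ldl Mean LDL of each cohort (mmol/L).
#' @param n_trials,trial_n_per_arm Number of trials and per-arm size.
#' @param trial_baseline_ldl,trial_delta_ldl Control-arm LDL and
#'   between-arm LDL difference `Y` per trial (mmol/L).
#' @param n_placebo_trials How many trials are placebo-controlled (the
#'   rest compare two statin intensities).
#' @param n_case_control,cc_cases,cc_controls Number and size of
#'   case-control studies.
#' @param cc_ldl Source-population LDL for each case-control study.
#' @return A list understood by [simulate_paper_like_collection()].
#' @export
collection_config <- function(n_cohorts = 3,
                              cohort_n = 12800,
                              cohort_ldl = seq(2.0, 5.0,
                                               length.out = n_cohorts),
                              n_trials = 8,
                              trial_n_per_arm = 3100,
                              trial_baseline_ldl = seq(3.3, 4.7,
                                                       length.out = n_trials),
                              trial_delta_ldl = seq(0.3, 1.8,
                                                    length.out = n_trials),
                              n_placebo_trials = 5,
                              n_case_control = 18,
                              cc_cases = 1550, cc_controls = 1550,
                              cc_ldl = seq(2.0, 5.0,
                                           length.out = max(n_case_control,
                                                            1))) {
  list(n_cohorts = n_cohorts, cohort_n = cohort_n, cohort_ldl = cohort_ldl,
       n_trials = n_trials, trial_n_per_arm = trial_n_per_arm,
       trial_baseline_ldl = trial_baseline_ldl,
       trial_delta_ldl = trial_delta_ldl,
       n_placebo_trials = n_placebo_trials,
       n_case_control = n_case_control,
       cc_cases = cc_cases, cc_controls = cc_controls, cc_ldl = cc_ldl)
}

#' Simulate a full paper-shaped study collection
#'
#' Generates cohorts, trials (whose arms are also emitted as separate
#' prospective cohorts) and case-control studies under one
#' [vulnerability_model()]. A single master seed fans out to per-study
#' child seeds by stable hashing of study ids, so adding or removing a
#' study does not perturb the others.
#'
#' @param model A [vulnerability_model()].
#' @param config A [collection_config()].
#' @param seed Master integer seed.
#' @return A list with `studies` (list of [study_record()]: cohorts, trial
#'   arms, case-control) and `trials` (list of [trial_record()]).
#' @export
simulate_paper_like_collection <- function(model,
                                           config = collection_config(),
                                           seed = 1L) {
  stopifnot(inherits(model, "vulnerability_model"))
  studies <- list()
  trials <- list()
  for (i in seq_len(config$n_cohorts)) {
    id <- sprintf("cohort_%02d", i)
    studies[[id]] <- simulate_cohort(model, config$cohort_n,
                                     config$cohort_ldl[i],
                                     seed = .child_seed(seed, id), id = id)
  }
  for (i in seq_len(config$n_trials)) {
    id <- sprintf("trial_%02d", i)
    ct <- if (i <= config$n_placebo_trials) "placebo" else "less_intensive"
    tr <- simulate_trial(model, config$trial_n_per_arm,
                         config$trial_baseline_ldl[i],
                         config$trial_delta_ldl[i],
                         seed = .child_seed(seed, id), id = id,
                         control_type = ct)
    trials[[id]] <- tr
    for (arm in names(tr$arms)) studies[[tr$arms[[arm]]$id]] <- tr$arms[[arm]]
  }
  for (i in seq_len(config$n_case_control)) {
    id <- sprintf("cc_%02d", i)
    studies[[id]] <- simulate_case_control(model, config$cc_cases,
                                           config$cc_controls,
                                           config$cc_ldl[i],
                                           seed = .child_seed(seed, id),
                                           id = id)
  }
  list(studies = unname(studies), trials = unname(trials))
}

#' Read a simulation configuration from a YAML file
#'
#' Recognized keys match the arguments of [vulnerability_model()] and
#' [collection_config()], plus `seed`. Unknown keys are an error.
#'
#' @param path Path to a YAML (key/value) configuration file.
#' @return A list with elements `model` ([vulnerability_model()]), `config`
#'   ([collection_config()]) and `seed`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model_keys <- c("baseline_risk", "beta_L", "beta_GL", "ldl_null",
                  "allele_freq", "ldl_ref", "ldl_range")
  config_keys <- names(formals(collection_config))
  unknown <- setdiff(names(raw), c(model_keys, config_keys, "seed"))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model <- do.call(vulnerability_model, raw[intersect(names(raw),
                                                      model_keys)])
  config <- do.call(collection_config, raw[intersect(names(raw),
                                                     config_keys)])
  list(model = model, config = config,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}
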