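#' Construct a 2x2 event table
#'
#' The atom of every effect estimate in the package: event and non-event
#' counts for an "exposed" row (e.g. 719Arg carriers, or the active arm of a
#' trial) and an "unexposed" row (non-carriers, or the control arm). For
#' case-control designs the columns are cases/controls rather than
#' events/at-risk, which changes which measure ([odds_ratio()]) is valid.
#'
#' @param events_exposed,nonevents_exposed,events_unexposed,nonevents_unexposed
#'   Non-negative integer counts (the classical a, b, c, d cells).
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(20, 80, 10, 90)
#' @export
two_by_two <- function(events_exposed, nonevents_exposed,
                       events_unexposed, nonevents_unexposed) {
  cells <- c(a = events_exposed, b = nonevents_exposed,
             c = events_unexposed, d = nonevents_unexposed)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("all four cell counts must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(cells - round(cells)) > 1e-8)) {
    stop("cell counts must be integers", call. = FALSE)
  }
  structure(as.list(round(cells)), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(unlist(x), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("events", "non-events")))
  print(m)
  invisible(x)
}

# Haldane-Anscombe continuity correction: +0.5 to every cell when any is zero.
.correct_cells <- function(x, correction) {
  cells <- unlist(x[c("a", "b", "c", "d")])
  if (any(cells == 0)) {
    if (!correction) {
      stop("zero cell encountered with continuity correction disabled",
           call. = FALSE)
    }
    cells <- cells + 0.5
    attr(cells, "corrected") <- TRUE
  } else {
    attr(cells, "corrected") <- FALSE
  }
  cells
}

#' Construct a log-scale effect estimate
#'
#' The common currency of the package: a point estimate on the natural-log
#' scale with its standard error. Confidence limits are always symmetric
#' around `log_point` on the log scale.
#'
#' @param log_point Point estimate on the natural-log scale.
#' @param se Standard error of `log_point` (> 0).
#' @param ci_level Two-sided confidence level, default `0.95`.
#' @param measure_label One of `"RR"`, `"OR"`, `"ratio_of_RR"`.
#' @param scale Either `"raw"` or `"per_mmol"`; pooled analyses refuse to mix
#'   the two (see [standardize_per_mmol()]).
#' @return An object of class `effect_estimate` with fields `log_point`,
#'   `se`, `ci_level`, `measure_label`, `scale`.
#' @export
effect_estimate <- function(log_point, se, ci_level = 0.95,
                            measure_label = c("RR", "OR", "ratio_of_RR"),
                            scale = c("raw", "per_mmol")) {
  measure_label <- match.arg(measure_label)
  scale <- match.arg(scale)
  if (!is.finite(log_point)) stop("log_point must be finite", call. = FALSE)
  if (!is.finite(se) || se <= 0) {
    stop("se must be a positive finite number", call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(log_point = log_point, se = se, ci_level = ci_level,
                 measure_label = measure_label, scale = scale),
            class = "effect_estimate")
}

#' Exponentiated confidence interval of an effect estimate
#'
#' @param object An `effect_estimate`.
#' @param parm Ignored.
#' @param level Confidence level; defaults to the estimate's own `ci_level`.
#' @param ... Ignored.
#' @return Named numeric vector `c(point, lower, upper)` on the ratio scale.
#' @export
confint.effect_estimate <- function(object, parm, level = object$ci_level,
                                    ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  object$log_point <- unname(object$log_point)
  object$se <- unname(object$se)
  c(point = exp(object$log_point),
    lower = exp(object$log_point - z * object$se),
    upper = exp(object$log_point + z * object$se))
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  ci <- confint(x)
  cat(sprintf("%s %s: %.*f (%.0f%% CI %.*f-%.*f), log SE %.*f\n",
              x$measure_label,
              if (x$scale == "per_mmol") "per mmol/L" else "",
              digits, ci["point"], 100 * x$ci_level,
              digits, ci["lower"], digits, ci["upper"],
              digits, x$se))
  invisible(x)
}

#' Unadjusted relative risk from a 2x2 table
#'
#' Risk ratio for the exposed vs unexposed row of a prospective (cohort or
#' trial-arm) table, with the standard delta-method log standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @param table A [two_by_two()] with rows events/at-risk.
#' @param correction Apply the Haldane-Anscombe +0.5 correction to all four
#'   cells when any cell is zero (default `TRUE`). With `correction = FALSE`
#'   a zero cell is an error.
#' @param ci_level Confidence level for downstream CIs.
#' @return An [effect_estimate()] with `measure_label = "RR"`.
#' @examples
#' relative_risk(two_by_two(20, 80, 10, 90))   # RR = 2
#' @export
relative_risk <- function(table, correction = TRUE, ci_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop("invalid table: a row total is zero", call. = FALSE)
  }
  cl <- .correct_cells(table, correction)
  a <- cl[["a"]]; b <- cl[["b"]]; c <- cl[["c"]]; d <- cl[["d"]]
  lp <- log((a / (a + b)) / (c / (c + d)))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  effect_estimate(lp, se, ci_level = ci_level, measure_label = "RR")
}

#' Unadjusted odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Woolf log standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. Intended for case-control tables, where it
#' approximates the relative risk when events are rare; downstream pooling
#' treats the two measures as interchangeable on the log scale.
#'
#' @inheritParams relative_risk
#' @return An [effect_estimate()] with `measure_label = "OR"`.
#' @export
odds_ratio <- function(table, correction = TRUE, ci_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop("invalid table: a row total is zero", call. = FALSE)
  }
  cl <- .correct_cells(table, correction)
  a <- cl[["a"]]; b <- cl[["b"]]; c <- cl[["c"]]; d <- cl[["d"]]
  lp <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  effect_estimate(lp, se, ci_level = ci_level, measure_label = "OR")
}

#' Genotype counts for a biallelic SNP
#'
#' @param n_homozygous_variant,n_heterozygous,n_homozygous_reference
#'   Non-negative counts of the three genotypes (e.g. Arg/Arg, Arg/Trp,
#'   Trp/Trp for KIF6 Trp719Arg). Carriers = homozygous variant +
#'   heterozygous.
#' @return An object of class `genotype_counts`.
#' @export
genotype_counts <- function(n_homozygous_variant, n_heterozygous,
                            n_homozygous_reference) {
  g <- c(vv = n_homozygous_variant, vr = n_heterozygous,
         rr = n_homozygous_reference)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("genotype counts must be finite and non-negative", call. = FALSE)
  }
  if (sum(g) <= 0) stop("total genotype count must be positive", call. = FALSE)
  structure(as.list(round(g)), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotypes: %d var/var, %d var/ref, %d ref/ref (carrier freq %.3f)\n",
              x$vv, x$vr, x$rr, (x$vv + x$vr) / (x$vv + x$vr + x$rr)))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of observed genotype counts against the p^2, 2pq,
#' q^2 proportions implied by the observed allele frequency, on 1 degree of
#' freedom.
#'
#' @param g A [genotype_counts()] object.
#' @return A list with `statistic`, `df` (always 1) and `p`.
#' @examples
#' hwe_chisq(genotype_counts(30, 40, 30))  # X2 = 4, p ~ 0.0455
#' @export
hwe_chisq <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  n <- g$vv + g$vr + g$rr
  p <- (2 * g$vv + g$vr) / (2 * n)  # variant allele frequency
  if (p <= 0 || p >= 1) {
    stop("monomorphic sample: HWE test undefined", call. = FALSE)
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(g$vv, g$vr, g$rr)
  statistic <- sum((observed - expected)^2 / expected)
  list(statistic = statistic, df = 1,
       p = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Recover a log-scale effect estimate from a published point and CI
#'
#' Many study-level analyses start from printed ratio estimates with
#' confidence limits rather than raw counts. Assuming the interval is
#' symmetric on the log scale, the standard error is
#' `(log(hi) - log(lo)) / (2 z)`.
#'
#' @param point,lo,hi Published ratio estimate and CI bounds, all > 0 with
#'   `lo <= point <= hi` and `lo < hi`.
#' @param ci_level Level of the published interval, default 0.95.
#' @param measure_label Measure of the published estimate.
#' @return An [effect_estimate()].
#' @examples
#' estimate_from_ci(0.73, 0.66, 0.80)
#' @export
estimate_from_ci <- function(point, lo, hi, ci_level = 0.95,
                             measure_label = "RR") {
  if (any(c(point, lo, hi) <= 0)) {
    stop("point and CI bounds must be positive", call. = FALSE)
  }
  if (lo > point || point > hi) {
    stop("need lo <= point <= hi", call. = FALSE)
  }
  if (lo == hi) stop("degenerate CI implies zero standard error", call. = FALSE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  effect_estimate(log(point), (log(hi) - log(lo)) / (2 * z),
                  ci_level = ci_level, measure_label = measure_label)
}
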