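#' @keywords internal
.check_estimates <- function(estimates) {
  if (length(estimates) == 0) stop("no estimates to pool", call. = FALSE)
  ok <- vapply(estimates, inherits, logical(1), what = "effect_estimate")
  if (!all(ok)) stop("all elements must be effect_estimate objects",
                     call. = FALSE)
  scales <- unique(vapply(estimates, `[[`, character(1), "scale"))
  if (length(scales) > 1) {
    stop("refusing to pool a mixture of raw and per-mmol/L estimates",
         call. = FALSE)
  }
  invisible(scales)
}

.meta_result <- function(log_point, se, k, Q, tau_squared, weights,
                         template, label = NULL) {
  df <- k - 1L
  i2 <- if (k < 2 || !is.finite(Q)) {
    NA_real_
  } else if (Q <= df) 0 else 100 * (Q - df) / Q
  pooled <- effect_estimate(log_point, se,
                            ci_level = template$ci_level,
                            measure_label = if (is.null(label))
                              template$measure_label else label,
                            scale = template$scale)
  structure(list(pooled = pooled, k = as.integer(k), Q = Q,
                 df = as.integer(df), i_squared = i2,
                 tau_squared = tau_squared, weights = weights),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  ci <- confint(x$pooled)
  cat(sprintf("Random/fixed-effect pool of k = %d studies\n", x$k))
  cat(sprintf("  pooled %s = %.*f (%.0f%% CI %.*f-%.*f)\n",
              x$pooled$measure_label, digits, ci["point"],
              100 * x$pooled$ci_level, digits, ci["lower"],
              digits, ci["upper"]))
  cat(sprintf("  Q = %.*f on %d df, I2 = %s%%, tau2 = %s\n",
              digits, x$Q, x$df,
              ifelse(is.na(x$i_squared), "NA", format(round(x$i_squared, 1))),
              ifelse(is.na(x$tau_squared), "NA",
                     format(signif(x$tau_squared, 4)))))
  invisible(x)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weighted mean of log effects with weights `1/se^2`; also the internal
#' first pass of the DerSimonian-Laird estimator, so Cochran's Q is computed
#' here.
#'
#' @param estimates List of [effect_estimate()] objects on a common scale.
#' @return A `meta_result` with fields `pooled` (an `effect_estimate`), `k`,
#'   `Q`, `df`, `i_squared`, `tau_squared` (0 by construction) and the
#'   per-study `weights` (which sum to the inverse of the pooled variance).
#' @export
pool_fixed <- function(estimates) {
  .check_estimates(estimates)
  y <- vapply(estimates, `[[`, numeric(1), "log_point")
  v <- vapply(estimates, `[[`, numeric(1), "se")^2
  w <- 1 / v
  yhat <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yhat)^2)
  .meta_result(yhat, 1 / sqrt(sum(w)), length(y), Q,
               tau_squared = 0, weights = w, template = estimates[[1]])
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance random-effects meta-analysis with the moment-based
#' between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`
#' from the fixed-effect pass, then re-weighting by `1/(se^2 + tau2)`.
#' Heterogeneity is summarized by Cochran's Q and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' A single estimate passes through unchanged with `tau_squared` and
#' `i_squared` reported as `NA` (not estimable).
#'
#' @inheritParams pool_fixed
#' @return A `meta_result`; see [pool_fixed()].
#' @examples
#' es <- list(effect_estimate(0, 0.1), effect_estimate(0.4, 0.1))
#' pool_random_effects(es)  # tau2 = 0.07, pooled log effect 0.2
#' @export
pool_random_effects <- function(estimates) {
  .check_estimates(estimates)
  k <- length(estimates)
  fe <- pool_fixed(estimates)
  if (k == 1L) {
    return(.meta_result(fe$pooled$log_point, fe$pooled$se, 1L, Q = 0,
                        tau_squared = NA_real_, weights = fe$weights,
                        template = estimates[[1]]))
  }
  y <- vapply(estimates, `[[`, numeric(1), "log_point")
  v <- vapply(estimates, `[[`, numeric(1), "se")^2
  w <- 1 / v
  tau2 <- max(0, (fe$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (v + tau2)
  yhat <- sum(wstar * y) / sum(wstar)
  .meta_result(yhat, 1 / sqrt(sum(wstar)), k, fe$Q,
               tau_squared = tau2, weights = wstar,
               template = estimates[[1]])
}
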