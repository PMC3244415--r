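#' Attach a study-level moderator to an effect estimate
#'
#' @param estimate An [effect_estimate()].
#' @param moderator Finite numeric study-level covariate (here: mean LDL in
#'   mmol/L, the study baseline or average follow-up level).
#' @return An object of class `moderated_estimate`.
#' @export
moderated_estimate <- function(estimate, moderator) {
  stopifnot(inherits(estimate, "effect_estimate"))
  if (!is.finite(moderator)) stop("moderator must be finite", call. = FALSE)
  structure(list(estimate = estimate, moderator = moderator),
            class = "moderated_estimate")
}

# Weighted fit at a fixed tau2. Returns coefficients, their covariance and
# the marginal precision matrix pieces needed by the tau2 estimators.
.wls_fit <- function(y, v, X, tau2) {
  w <- 1 / (v + tau2)
  M <- crossprod(X, w * X)
  Minv <- solve(M)
  beta <- drop(Minv %*% crossprod(X, w * y))
  list(beta = beta, vcov = Minv, w = w)
}

# Method-of-moments tau2 (the Q-based generalization of DerSimonian-Laird
# to a design matrix): fit at tau2 = 0, compare the residual Q to its
# expectation under homogeneity.
.tau2_mom <- function(y, v, X) {
  k <- length(y); p <- ncol(X)
  f <- .wls_fit(y, v, X, 0)
  r <- y - drop(X %*% f$beta)
  QE <- sum(f$w * r^2)
  W <- diag(f$w, k)
  denom <- sum(f$w) - sum(diag(f$vcov %*% crossprod(X, f$w^2 * X)))
  max(0, (QE - (k - p)) / denom)
}

# Restricted-likelihood score for tau2 (derivative of the REML
# log-likelihood with respect to the between-study variance).
.reml_score <- function(tau2, y, v, X) {
  k <- length(y)
  w <- 1 / (v + tau2)
  WX <- w * X
  P <- diag(w, k) - WX %*% solve(crossprod(X, WX)) %*% t(WX)
  Py <- drop(P %*% y)
  -0.5 * sum(diag(P)) + 0.5 * sum(Py^2)
}

# REML tau2: root of the restricted score, found by safeguarded Brent
# root-finding after bracketing (plain Fisher scoring can cycle around the
# optimum on data like these, where tau2 is small relative to the
# within-study variances). The boundary estimate 0 is returned when the
# score is non-positive there.
.tau2_reml <- function(y, v, X, tol = 1e-8, maxit = 100L, start = NULL) {
  sc0 <- .reml_score(0, y, v, X)
  if (sc0 <= 0) return(list(tau2 = 0, iter = 1L))
  upper <- max(if (is.null(start)) .tau2_mom(y, v, X) else start,
               stats::var(y), 1e-4)
  it <- 0L
  while (.reml_score(upper, y, v, X) > 0) {
    upper <- 2 * upper
    it <- it + 1L
    if (it > maxit) {
      stop(sprintf(
        "REML estimation of tau2 did not converge (no root below %.6g)",
        upper), call. = FALSE)
    }
  }
  root <- stats::uniroot(.reml_score, c(0, upper), y = y, v = v, X = X,
                         tol = tol, maxiter = maxit)
  list(tau2 = max(0, root$root), iter = root$iter)
}

#' Random-effects meta-regression of log effects on a moderator
#'
#' Fits the mixed model `y_i = b0 + b1 x_i + u_i + e_i` with known
#' within-study variances `Var(e_i) = se_i^2` and between-study variance
#' `Var(u_i) = tau2`, estimated by restricted maximum likelihood (Fisher
#' scoring, the default) or by the non-iterative method of moments.
#' Coefficients are weighted least squares at the estimated `tau2` with
#' weights `1/(se_i^2 + tau2)`.
#'
#' The between-study variance of the intercept-only model is refitted under
#' the same method and reported as `tau_squared_null`, so that the
#' variance-explained statistic [r_squared_explained()] compares like with
#' like.
#'
#' @param estimates List of [effect_estimate()] objects, or a list of
#'   [moderated_estimate()] objects (in which case `moderator` is taken from
#'   them).
#' @param moderator Numeric vector of study-level covariate values (mean LDL
#'   in mmol/L), one per estimate; not all equal.
#' @param method `"reml"` (default) or `"mom"`.
#' @param ci_level Confidence level carried into the coefficient estimates.
#' @param tol,maxit REML convergence tolerance on `tau2` and iteration cap.
#' @return An object of class `metareg_result` with components `intercept`
#'   and `slope` (both [effect_estimate()]s on the log scale; the slope is a
#'   log ratio of RRs per mmol/L), `vcov` (2x2 coefficient covariance),
#'   `tau_squared_residual`, `tau_squared_null`, `r_squared` (percent of
#'   between-study variance explained, truncated to \[0, 100\]), `k`,
#'   `method`, and the data used.
#' @examples
#' es <- lapply(c(0.3, 0.5, 0.7), effect_estimate, se = 0.1)
#' fit_meta_regression(es, moderator = c(1, 2, 3))
#' @export
fit_meta_regression <- function(estimates, moderator = NULL,
                                method = c("reml", "mom"), ci_level = 0.95,
                                tol = 1e-8, maxit = 100L) {
  method <- match.arg(method)
  if (is.null(moderator) &&
      all(vapply(estimates, inherits, logical(1), "moderated_estimate"))) {
    moderator <- vapply(estimates, `[[`, numeric(1), "moderator")
    estimates <- lapply(estimates, `[[`, "estimate")
  }
  .check_estimates(estimates)
  k <- length(estimates)
  if (k < 3) stop("meta-regression needs at least 3 studies", call. = FALSE)
  if (length(moderator) != k || any(!is.finite(moderator))) {
    stop("moderator must be a finite vector matching the estimates",
         call. = FALSE)
  }
  if (diff(range(moderator)) == 0) {
    stop("moderator is constant: design matrix is rank deficient",
         call. = FALSE)
  }
  y <- vapply(estimates, `[[`, numeric(1), "log_point")
  v <- vapply(estimates, `[[`, numeric(1), "se")^2
  X <- cbind(intercept = 1, moderator = moderator)
  X0 <- X[, 1, drop = FALSE]

  if (method == "reml") {
    tau2 <- .tau2_reml(y, v, X, tol = tol, maxit = maxit)$tau2
    tau2_null <- .tau2_reml(y, v, X0, tol = tol, maxit = maxit)$tau2
  } else {
    tau2 <- .tau2_mom(y, v, X)
    tau2_null <- .tau2_mom(y, v, X0)
  }
  fit <- .wls_fit(y, v, X, tau2)
  fit$beta <- unname(fit$beta)
  ses <- unname(sqrt(diag(fit$vcov)))
  structure(list(
    intercept = effect_estimate(fit$beta[1], ses[1], ci_level = ci_level,
                                measure_label = "RR"),
    slope = effect_estimate(fit$beta[2], ses[2], ci_level = ci_level,
                            measure_label = "ratio_of_RR"),
    coefficients = fit$beta,
    vcov = fit$vcov,
    tau_squared_residual = tau2,
    tau_squared_null = tau2_null,
    r_squared = r_squared_explained(tau2_null, tau2),
    k = as.integer(k),
    method = method,
    data = list(y = y, v = v, moderator = moderator),
    ci_level = ci_level), class = "metareg_result")
}

#' @export
print.metareg_result <- function(x, digits = 3, ...) {
  sci <- confint(x$slope)
  cat(sprintf("Random-effects meta-regression (tau2 by %s), k = %d\n",
              toupper(x$method), x$k))
  cat(sprintf("  slope: ratio of RR per mmol/L = %.*f (%.0f%% CI %.*f-%.*f)\n",
              digits, sci["point"], 100 * x$ci_level,
              digits, sci["lower"], digits, sci["upper"]))
  cat(sprintf("  residual tau2 = %.4g, null tau2 = %.4g, R2 = %.1f%%\n",
              x$tau_squared_residual, x$tau_squared_null, x$r_squared))
  invisible(x)
}

#' Percent of between-study variance explained by a moderator
#'
#' `100 * (tau2_null - tau2_residual) / tau2_null`, truncated to \[0, 100\];
#' defined as 0 when the null-model variance is 0.
#'
#' @param tau_null Between-study variance of the intercept-only model (>= 0).
#' @param tau_resid Residual between-study variance of the moderated model
#'   (>= 0).
#' @return Percentage in \[0, 100\].
#' @export
r_squared_explained <- function(tau_null, tau_resid) {
  if (!is.finite(tau_null) || !is.finite(tau_resid) ||
      tau_null < 0 || tau_resid < 0) {
    stop("tau2 values must be finite and non-negative", call. = FALSE)
  }
  if (tau_null == 0) return(0)
  min(100, max(0, 100 * (tau_null - tau_resid) / tau_null))
}

#' Predicted effect at a moderator value
#'
#' Evaluates the fitted regression line `b0 + b1 x` with the standard error
#' from the full coefficient covariance (including the covariance term).
#'
#' @param fit A `metareg_result`.
#' @param x Moderator value (mmol/L).
#' @return An [effect_estimate()] for the predicted log effect at `x`.
#' @export
predict_at <- function(fit, x) {
  stopifnot(inherits(fit, "metareg_result"))
  cvec <- c(1, x)
  lp <- sum(cvec * fit$coefficients)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  effect_estimate(lp, se, ci_level = fit$ci_level, measure_label = "RR")
}
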