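# Independent brute-force oracles written straight from the textbook
# definitions, kept free of any package internals so they can vouch for the
# implementation.

# DerSimonian-Laird random-effects pool from first principles.
oracle_dl <- function(y, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  df <- length(y) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(mu = sum(ws * y) / sum(ws), se = sqrt(1 / sum(ws)),
       Q = Q, tau2 = tau2,
       i2 = if (Q <= df) 0 else 100 * (Q - df) / Q)
}

# Method-of-moments meta-regression (Q-based tau2 with a design matrix),
# coefficients by generalized least squares at the moment estimate.
oracle_mom_metareg <- function(y, se, x) {
  X <- cbind(1, x)
  k <- length(y); p <- 2
  W <- diag(1 / se^2)
  b0 <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  r <- y - X %*% b0
  QE <- drop(t(r) %*% W %*% r)
  denom <- sum(diag(W)) -
    sum(diag(solve(t(X) %*% W %*% X) %*% (t(X) %*% W %*% W %*% X)))
  tau2 <- max(0, (QE - (k - p)) / denom)
  Ws <- diag(1 / (se^2 + tau2))
  V <- unname(solve(t(X) %*% Ws %*% X))
  b <- V %*% t(X) %*% Ws %*% y
  list(beta = unname(drop(b)), vcov = V, tau2 = tau2)
}

# Negative restricted log-likelihood of the mixed meta-regression model,
# for checking the REML tau2 by direct numeric optimization.
oracle_reml_nll <- function(tau2, y, se, X) {
  V <- diag(se^2 + tau2)
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  b <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  0.5 * (determinant(V)$modulus + determinant(M)$modulus +
           drop(t(r) %*% Vi %*% r))
}

expect_estimate_equal <- function(e, log_point, se, tol = 1e-10) {
  expect_equal(e$log_point, log_point, tolerance = tol)
  expect_equal(e$se, se, tolerance = tol)
}
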