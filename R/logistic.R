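# Weighted ridge logistic regression by Newton / IRLS.
#
# Minimises  -sum_i w_i [y_i eta_i - log(1 + exp(eta_i))] + (lambda/2)|beta|^2
# with eta = b0 + X beta; the intercept is unpenalised.  Deterministic,
# converges to machine precision, and the solution depends on the weights
# only through the weighted log-likelihood, so duplicating a case while
# halving its weight leaves the fit bit-for-bit unchanged.  The small ridge
# term keeps perfectly separable data finite.
ridge_logistic <- function(X, y, weights = NULL, lambda = 1e-4,
                           max_iter = 100, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    ctg_error("outcome has a single class; logistic fit is degenerate",
              "ctg_degenerate_fit_error")
  if (is.null(weights)) weights <- rep(1, n)
  Z <- cbind(`(intercept)` = 1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- numeric(p + 1)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    g <- crossprod(Z, weights * (y - mu)) - pen %*% beta
    wv <- pmax(weights * mu * (1 - mu), 1e-10)
    H <- crossprod(Z, Z * wv) + pen
    step <- solve(H, g)
    beta_new <- beta + step
    eta_new <- drop(Z %*% beta_new)
    dev <- -2 * sum(weights * (y * eta_new - log1p(exp(pmin(eta_new, 700))))) +
      lambda * sum(beta_new[-1]^2)
    # halve the step while the penalised deviance worsens
    halvings <- 0
    while (!is.finite(dev) || dev > dev_old + 1e-8) {
      step <- step / 2
      beta_new <- beta + step
      eta_new <- drop(Z %*% beta_new)
      dev <- -2 * sum(weights * (y * eta_new - log1p(exp(pmin(eta_new, 700))))) +
        lambda * sum(beta_new[-1]^2)
      halvings <- halvings + 1
      if (halvings > 30) break
    }
    converged <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    dev_old <- dev
    if (converged) break
  }
  list(intercept = beta[1], coef = beta[-1], lambda = lambda, iter = it)
}

# Column-wise standardisation with stored center/scale; zero-variance
# columns keep scale 1 so constants pass through unchanged.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2, scaler$center, "-"), 2, scaler$scale, "/")
}
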