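# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# plain summed trapezoid rule
trapzOracle <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Receptor-noise-limited chromatic distance via the noise-weighted
# projection orthogonal to the achromatic direction (matrix formulation):
# dS^2 = df' (D^-1 - D^-1 1 1' D^-1 / (1' D^-1 1)) df, D = diag(w^2).
rnlMatrixOracle <- function(df, w) {
  Dinv <- diag(1 / w^2, length(w))
  one <- rep(1, length(w))
  M <- Dinv - (Dinv %*% one %*% t(one) %*% Dinv) /
    drop(t(one) %*% Dinv %*% one)
  sqrt(drop(t(df) %*% M %*% df))
}

# Efron-tie Cox partial log-likelihood for a single numeric covariate,
# written directly from the definition (no shared code with coxPH).
efronLogLikOracle <- function(beta, time, status, x) {
  ll <- 0
  for (t in unique(time[status == 1])) {
    dead <- which(status == 1 & time == t)
    risk <- which(time >= t)
    d <- length(dead)
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(exp(beta * x[risk])) -
                     (l / d) * sum(exp(beta * x[dead])))
    }
  }
  ll
}

# Laplace approximation to the random-intercept logistic marginal
# log-likelihood, with the mode found by optimize() and the curvature by a
# central finite difference (independent of the package's Newton code).
laplaceLogLikOracle <- function(beta, sigma, y, X, group) {
  eta0 <- drop(X %*% beta)
  tot <- 0
  for (g in unique(group)) {
    i <- group == g
    h <- function(u)
      sum(y[i] * (eta0[i] + sigma * u) -
          log1p(exp(eta0[i] + sigma * u))) - u^2 / 2
    opt <- optimize(h, c(-15, 15), maximum = TRUE)
    u0 <- opt$maximum
    eps <- 1e-4
    h2 <- (h(u0 + eps) - 2 * h(u0) + h(u0 - eps)) / eps^2
    tot <- tot + opt$objective + 0.5 * log(2 * pi / (-h2)) -
      0.5 * log(2 * pi)
  }
  tot
}

# Full maximum-likelihood gamma GLM (log link) by direct optimisation of
# the gamma density over coefficients and shape jointly.
gammaMLOracle <- function(y, X) {
  nll <- function(par) {
    beta <- par[-length(par)]
    shape <- exp(par[length(par)])
    mu <- exp(drop(X %*% beta))
    -sum(dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  }
  start <- c(log(mean(y)), rep(0, ncol(X) - 1), 0)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  list(beta = opt$par[-length(opt$par)], shape = exp(opt$par[length(opt$par)]))
}
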