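## ---- Gauss-Hermite nodes ---------------------------------------------------

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule (weight
#' `exp(-t^2)`), computed by the Golub-Welsch eigendecomposition of the
#' Jacobi matrix. Used by the adaptive-quadrature mixed-model fitter.
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`, each length `n`.
#' @export
gaussHermite <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("need at least one quadrature node")
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1L) / 2)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  o <- order(e$values)
  list(nodes = e$values[o], weights = sqrt(pi) * e$vectors[1L, o]^2)
}

## Numerically stable log(1 + exp(x)).
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## ---- IRLS fixed-effects GLMs ----------------------------------------------

## One IRLS engine for the two families used here. Returns estimates,
## covariance, convergence and the final linear predictor.
irlsFit <- function(y, X, family = c("binomial", "gamma"),
                    tol = 1e-10, maxIter = 100L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- numeric(p)
  if (family == "gamma") beta[1L] <- log(mean(y))  # intercept start
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    if (family == "binomial") {
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      w <- pmax(w, 1e-12)
      z <- eta + (y - mu) / w
    } else {
      mu <- exp(eta)
      w <- rep(1, length(y))       # gamma log link: (dmu/deta)^2 / V = 1
      z <- eta + (y - mu) / mu
    }
    wx <- X * w
    newBeta <- drop(solve(crossprod(X, wx), crossprod(wx, z)))
    if (max(abs(newBeta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- newBeta
      converged <- TRUE
      break
    }
    beta <- newBeta
  }
  eta <- drop(X %*% beta)
  mu <- if (family == "binomial") stats::plogis(eta) else exp(eta)
  w <- if (family == "binomial") pmax(mu * (1 - mu), 1e-12)
       else rep(1, length(y))
  ## score of the estimating equations at the optimum (separation guard)
  score <- if (family == "binomial") drop(crossprod(X, y - mu))
           else drop(crossprod(X, (y - mu) / mu))
  separated <- family == "binomial" && any(abs(beta) > 12)
  list(beta = stats::setNames(beta, colnames(X)),
       cov = solve(crossprod(X, X * w)),
       mu = mu, score = score,
       converged = converged && !separated,
       separated = separated, iterations = iter)
}

## ---- Logistic GLM / GLMM --------------------------------------------------

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Log-likelihood of a binomial (logit) model with linear predictor
#' `X beta + sigma u_g`, the group effects `u_g` standard normal and
#' integrated out by adaptive Gauss-Hermite quadrature: per group, the
#' integrand's mode and curvature are located by Newton steps and the
#' quadrature nodes are centred and scaled there. With one node this is
#' exactly the Laplace approximation; with `sigma = 0` it is the ordinary
#' binomial log-likelihood.
#'
#' @param beta fixed-effect coefficients (matching `ncol(X)`).
#' @param sigma random-intercept SD (>= 0).
#' @param y 0/1 response; @param X design matrix; @param group group labels.
#' @param nodes number of quadrature nodes (default 15).
#' @return scalar log-likelihood.
#' @export
logisticMarginalLogLik <- function(beta, sigma, y, X, group, nodes = 15L,
                                   idx = NULL, gh = NULL) {
  eta0 <- drop(as.matrix(X) %*% beta)
  if (sigma == 0 || is.null(group))
    return(sum(y * eta0 - log1pexp(eta0)))
  if (is.null(gh)) gh <- gaussHermite(nodes)
  if (is.null(idx)) idx <- split(seq_along(y), group)
  total <- 0
  for (i in idx) {
    yi <- y[i]; ei <- eta0[i]
    ## Newton for the mode of h(u) = loglik_g(u) - u^2/2
    u <- 0
    for (it in 1:50) {
      p <- stats::plogis(ei + sigma * u)
      g <- sigma * sum(yi - p) - u
      h <- -sigma^2 * sum(p * (1 - p)) - 1
      step <- g / h
      u <- u - step
      if (abs(step) < 1e-10) break
    }
    p <- stats::plogis(ei + sigma * u)
    shat <- 1 / sqrt(sigma^2 * sum(p * (1 - p)) + 1)
    t <- u + sqrt(2) * shat * gh$nodes
    et <- outer(ei, sigma * t, `+`)   # members x nodes
    hvals <- colSums(yi * et - log1pexp(et)) - t^2 / 2
    expo <- hvals + gh$nodes^2 + log(gh$weights)
    m <- max(expo)
    total <- total + log(sqrt(2) * shat / sqrt(2 * pi)) + m +
      log(sum(exp(expo - m)))
  }
  total
}

#' Logistic regression with an optional single random intercept
#'
#' Plain binomial GLM (iteratively reweighted least squares) when `group`
#' is `NULL`, otherwise a logistic mixed model with one Gaussian random
#' intercept per group, fitted by maximising the adaptive Gauss-Hermite
#' marginal likelihood ([logisticMarginalLogLik()]) over the fixed effects
#' and `log(sigma)`. Standard errors come from the observed information
#' (numerical Hessian of the marginal log-likelihood for the mixed model),
#' with Wald z and two-sided p values.
#'
#' Complete separation is flagged as non-convergence rather than reported
#' as estimates; a random-intercept SD estimated at the zero boundary is
#' reported as 0 with a note.
#'
#' @param y 0/1 response vector.
#' @param X design matrix including the intercept column.
#' @param group optional grouping labels (family, transect, ...).
#' @param nodes adaptive quadrature nodes (default 15).
#' @param sigmaFixed optionally fix the random-intercept SD (e.g. 0 to
#'   force the marginal-likelihood machinery onto the GLM solution).
#' @param formula character description stored in the fit.
#' @return a [ModelFit].
#' @export
fitLogistic <- function(y, X, group = NULL, nodes = 15L, sigmaFixed = NULL,
                        formula = "y ~ X") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("response has fewer than 2 distinct values")
  if (nodes < 1L) stop("quadrature_nodes must be >= 1")
  notes <- character()
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(p))

  if (!is.null(group) && length(unique(group)) < 2L) {
    notes <- c(notes, "fewer than 2 groups; fell back to plain GLM")
    group <- NULL
  }

  if (is.null(group) && is.null(sigmaFixed)) {
    f <- irlsFit(y, X, "binomial")
    if (f$separated)
      notes <- c(notes, "possible complete separation; estimates diverge")
    se <- sqrt(diag(f$cov))
    z <- f$beta / se
    return(new("ModelFit",
               estimates = f$beta, se = stats::setNames(se, names(f$beta)),
               z = z, p = 2 * stats::pnorm(-abs(z)),
               ranefSD = NA_real_, family = "binomial", link = "logit",
               dispersion = 1, n = length(y), nGroups = 0L,
               converged = f$converged, formula = formula, notes = notes))
  }

  ## mixed model (or sigma fixed): maximise the marginal likelihood
  start <- irlsFit(y, X, "binomial")$beta
  freeSigma <- is.null(sigmaFixed)
  idx <- if (!is.null(group)) split(seq_along(y), group)
  gh <- gaussHermite(nodes)
  negll <- function(beta, sigma)
    -logisticMarginalLogLik(beta, sigma, y, X, group, nodes,
                            idx = idx, gh = gh)
  ctl <- list(maxit = 300, reltol = 1e-11)
  if (freeSigma) {
    ## log-sigma bounded below: the likelihood is flat in log-sigma as
    ## sigma -> 0, so the boundary is handled explicitly
    opt <- stats::optim(c(start, log(0.5)),
                        function(par) negll(par[seq_len(p)],
                                            exp(par[p + 1L])),
                        method = "L-BFGS-B",
                        lower = c(rep(-Inf, p), log(1e-6)),
                        upper = c(rep(Inf, p), log(20)),
                        control = list(maxit = 300, factr = 1e4))
    beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
    sigma <- unname(exp(opt$par[p + 1L]))
  } else {
    opt <- stats::optim(start, function(par) negll(par, sigmaFixed),
                        method = "BFGS", control = ctl)
    beta <- stats::setNames(opt$par, colnames(X))
    sigma <- sigmaFixed
  }
  conv <- opt$convergence == 0 && max(abs(beta)) <= 12
  if (max(abs(beta)) > 12)
    notes <- c(notes, "possible complete separation; estimates diverge")
  ## observed information, central differences; near the sigma = 0 boundary
  ## the log-sigma direction is flat, so use the beta-only block there
  atBoundary <- freeSigma && sigma < 0.02
  if (atBoundary)
    notes <- c(notes, "random-intercept SD near the zero boundary")
  se <- NULL
  if (freeSigma && !atBoundary) {
    H <- numericHessian(function(par) -negll(par[seq_len(p)],
                                             exp(par[p + 1L])),
                        c(beta, log(sigma)))
    covAll <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(covAll) && all(diag(covAll)[seq_len(p)] > 0))
      se <- sqrt(diag(covAll)[seq_len(p)])
    else
      notes <- c(notes, "random-intercept SD weakly identified")
  }
  if (is.null(se)) {  # beta-only information at the fitted sigma
    H <- numericHessian(function(par) -negll(par, sigma), as.numeric(beta))
    covB <- tryCatch(solve(-H), error = function(e) NULL)
    if (is.null(covB) || any(diag(covB) <= 0)) {
      se <- rep(NA_real_, p)
      notes <- c(notes, "information matrix not positive definite")
      conv <- FALSE
    } else se <- sqrt(diag(covB))
  }
  se <- stats::setNames(se, colnames(X))
  z <- beta / se
  new("ModelFit",
      estimates = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
      ranefSD = sigma, family = "binomial", link = "logit",
      dispersion = 1, n = length(y),
      nGroups = if (is.null(group)) 0L else length(unique(group)),
      converged = conv, formula = formula, notes = notes)
}

## Central-difference Hessian of a scalar function (small dimension).
numericHessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  hstep <- eps * pmax(1, abs(x))
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k)
    ei[i] <- hstep[i]; ej[j] <- hstep[j]
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * hstep[i] * hstep[j])
  }
  H
}

#' Gamma regression with log link
#'
#' Gamma GLM with logarithmic link, fitted by IRLS; the dispersion is the
#' Pearson estimator, and Wald z / p values use the estimated dispersion.
#' The response must be strictly positive -- replace structural zeros first
#' with [replaceZeros()].
#'
#' @param y strictly positive response.
#' @param X design matrix including the intercept column.
#' @param formula character description stored in the fit.
#' @return a [ModelFit] with the Pearson `dispersion` filled in.
#' @export
fitGammaLog <- function(y, X, formula = "y ~ X") {
  y <- as.numeric(y)
  if (any(y <= 0))
    stop("gamma response must be strictly positive (replaceZeros() first)")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  f <- irlsFit(y, X, "gamma")
  phi <- sum((y - f$mu)^2 / f$mu^2) / (length(y) - ncol(X))
  se <- sqrt(diag(f$cov) * phi)
  z <- f$beta / se
  new("ModelFit",
      estimates = f$beta, se = stats::setNames(se, names(f$beta)),
      z = z, p = 2 * stats::pnorm(-abs(z)),
      ranefSD = NA_real_, family = "gamma", link = "log",
      dispersion = phi, n = length(y), nGroups = 0L,
      converged = f$converged, formula = formula, notes = character())
}
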