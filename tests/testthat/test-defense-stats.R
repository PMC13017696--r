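test_that("centring and zero replacement follow their definitions", {
  expect_equal(as.numeric(centerValues(c(1, 2, 3))), c(-1, 0, 1))
  expect_equal(as.numeric(centerValues(rep(4, 5))), rep(0, 5))
  set.seed(8)
  v <- rnorm(100, 3, 2)
  expect_lt(abs(mean(centerValues(v))), 1e-12)
  expect_equal(attr(centerValues(v), "center"), mean(v))
  expect_error(centerValues(numeric()), "empty")

  expect_equal(replaceZeros(c(0, 0.4, 0)), c(0.001, 0.4, 0.001))
  expect_equal(replaceZeros(c(0.2, 0.4)), c(0.2, 0.4))
  expect_equal(replaceZeros(rep(0, 3)), rep(0.001, 3))
  expect_equal(replaceZeros(c(0, 1), epsilon = 0.01), c(0.01, 1))
  expect_error(replaceZeros(c(-1, 0)), ">= 0")
})

test_that("logistic GLM path solves the score equations and matches stats::glm", {
  set.seed(14)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.4 + 0.9 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  ours <- fitLogistic(y, X)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(ours@se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  # score equations at the optimum
  mu <- plogis(drop(X %*% coef(ours)))
  expect_lt(max(abs(crossprod(X, y - mu))), 1e-8)
  expect_true(all(mu > 0 & mu < 1))

  # centring identity: slope unchanged, intercept shifts by slope*mean
  xc <- as.numeric(centerValues(x))
  fc <- fitLogistic(y, cbind(`(Intercept)` = 1, x = xc))
  expect_equal(coef(fc)["x"], coef(ours)["x"], tolerance = 1e-8)
  expect_equal(unname(coef(fc)[1]),
               unname(coef(ours)[1] + coef(ours)["x"] * mean(x)),
               tolerance = 1e-8)
})

test_that("sigma fixed at zero reproduces the plain GLM through the marginal machinery", {
  set.seed(15)
  g <- rep(1:10, each = 8)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.5 + 0.6 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  glmFit <- fitLogistic(y, X)
  mixed0 <- fitLogistic(y, X, group = g, sigmaFixed = 0)
  expect_equal(coef(mixed0), coef(glmFit), tolerance = 1e-6)
})

test_that("one-node adaptive quadrature equals an independent Laplace oracle", {
  set.seed(16)
  g <- rep(1:12, each = 5)
  u <- rnorm(12, 0, 0.6)[g]
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(0.8 + 0.4 * x + u))
  X <- cbind(1, x)
  for (theta in list(c(0.5, 0.2, 0.4), c(1.0, 0.5, 0.8),
                     c(-0.3, 0.1, 1.5))) {
    expect_equal(
      logisticMarginalLogLik(theta[1:2], theta[3], y, X, g, nodes = 1),
      laplaceLogLikOracle(theta[1:2], theta[3], y, X, g),
      tolerance = 1e-6)
  }
})

test_that("the mixed fit matches lme4 and is stable in the node count", {
  skip_if_not_installed("lme4")
  set.seed(2)
  g <- rep(1:12, each = 5)
  u <- rnorm(12, 0, 0.5)[g]
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(1 + 0.5 * x + u))
  dat <- data.frame(y = y, x = x, g = g)
  ours <- fitLogistic(y, cbind(`(Intercept)` = 1, x = x), group = g,
                      nodes = 15)
  ref <- lme4::glmer(y ~ x + (1 | g), family = binomial, data = dat,
                     nAGQ = 15)
  expect_equal(unname(coef(ours)), unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  expect_equal(ours@ranefSD, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-3)
  expect_equal(unname(ours@se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3)

  # quadrature convergence: doubling the nodes moves nothing at 1e-6
  more <- fitLogistic(y, cbind(`(Intercept)` = 1, x = x), group = g,
                      nodes = 30)
  expect_lt(max(abs(coef(more) - coef(ours))), 1e-6)
  expect_lt(abs(more@ranefSD - ours@ranefSD), 1e-5)

  expect_error(fitLogistic(y, cbind(1, x), group = g, nodes = 0),
               "quadrature_nodes")
})

test_that("Wald test of a GLM slope is calibrated under the null", {
  set.seed(18)
  pv <- replicate(400, {
    x <- rnorm(250)
    y <- rbinom(250, 1, 0.5)
    fitLogistic(y, cbind(`(Intercept)` = 1, x = x))@p["x"]
  })
  expect_gt(mean(pv < 0.05), 0.03)
  expect_lt(mean(pv < 0.05), 0.07)
})

test_that("gamma log-link fit matches stats::glm and a full ML oracle", {
  set.seed(19)
  x <- rnorm(20)
  len <- rnorm(20, 22, 2)
  mu <- exp(0.5 + 0.3 * x + 0.05 * (len - 22))
  y <- rgamma(20, shape = 2, scale = mu / 2)
  X <- cbind(`(Intercept)` = 1, x = x, len = len - 22)
  ours <- fitGammaLog(y, X)
  ref <- glm(y ~ x + I(len - 22), family = Gamma(link = "log"),
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(ours@dispersion, summary(ref)$dispersion, tolerance = 1e-6)
  ml <- gammaMLOracle(y, X)
  expect_equal(unname(coef(ours)), ml$beta, tolerance = 1e-5)

  # degenerate constant response: intercept ln(c), slopes ~ 0
  yc <- rep(2.5, 20)
  fc <- fitGammaLog(yc, X)
  expect_equal(unname(coef(fc)[1]), log(2.5), tolerance = 1e-8)
  expect_lt(max(abs(coef(fc)[-1])), 1e-8)

  expect_error(fitGammaLog(c(0, 1, 2), cbind(1, 1:3)), "strictly positive")
})

test_that("gamma slope recovery on simulated volumes", {
  set.seed(20)
  est <- replicate(200, {
    x <- rnorm(500)
    mu <- exp(0.5 + 0.1 * x)
    y <- rgamma(500, shape = 2, scale = mu / 2)
    coef(fitGammaLog(y, cbind(1, x = x)))["x"]
  })
  expect_lt(abs(mean(est) - 0.1), 3 * sd(est) / sqrt(200))
})

test_that("the behaviour battery runs the requested models on valid records", {
  b <- genBehavior(seed = 7)
  fits <- behaviorAnalysis(b)
  expect_named(fits, c("uposture_ventral_color", "uposture_ventral_luminance",
                       "fluid_ventral_color", "fluid_ventral_luminance",
                       "volume_ventral_color", "volume_ventral_luminance"))
  fitsD <- behaviorAnalysis(b, dorsal = TRUE)
  expect_length(fitsD, 10L)
  # the dorsal-colour U-posture model is the plain-GLM member
  expect_equal(fitsD$uposture_dorsal_color@nGroups, 0L)
  expect_gt(fitsD$uposture_ventral_color@nGroups, 1L)
  # volume models always carry the length covariate
  expect_true("length_mm" %in% names(coef(fits$volume_ventral_color)))

  only <- behaviorAnalysis(b, models = "volume")
  expect_length(only, 2L)

  bad <- b; bad$fluid_volume[bad$fluid == "no"][1] <- 0.2
  expect_error(behaviorAnalysis(bad), "fluid_volume 0")
})

test_that("behaviour battery falls back to GLM with a single family", {
  b <- genBehavior(seed = 7)
  b$family_id <- 1L
  fits <- behaviorAnalysis(b, models = "uposture")
  expect_match(fits$uposture_ventral_color@notes, "fewer than 2 groups")
  expect_equal(fits$uposture_ventral_color@nGroups, 0L)
})

test_that("slope signs are recovered from a generator with opposed colour/luminance effects", {
  pars <- list(uposture_intercept = 1.2, uposture_color_slope = -0.6,
               uposture_luminance_slope = 0.5, family_sd = 0.3)
  signs <- sapply(1:40, function(i) {
    b <- genBehavior(nFamilies = 12L, perFamily = rep(10L, 12),
                     params = pars, seed = 300 + i)
    f <- behaviorAnalysis(b, models = "uposture")
    c(col = unname(coef(f$uposture_ventral_color)[2]),
      lum = unname(coef(f$uposture_ventral_luminance)[2]))
  })
  expect_gt(mean(signs["col", ] < 0), 0.9)
  expect_gt(mean(signs["lum", ] > 0), 0.9)
})

test_that("males are excluded when a sex column is present", {
  b <- genBehavior(seed = 7)
  b$sex <- "female"
  b$sex[1:4] <- "male"
  expect_message(fits <- behaviorAnalysis(b, models = "volume"),
                 "excluding 4 male")
  expect_equal(fits$volume_ventral_color@n, nrow(b) - 4L)
})
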