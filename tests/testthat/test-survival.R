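test_that("first-attack filter truncates branches at the first attack day", {
  # one branch of 10: deaths on days 2 and 4 among originals
  rec <- makeRecords(
    event_day = c(2L, 4L, rep(5L, 8L)),
    event = c("died", "died", rep("survived", 8L)),
    tree_id = 1L, group = "group10")
  f <- firstAttackFilter(rec)
  expect_equal(nrow(f), 10L)
  expect_equal(f$event[f$individual_id == 1], "died")       # day-2 death kept
  expect_equal(f$event[f$individual_id == 2], "survived")   # day-4 recoded
  expect_equal(f$event_day[f$individual_id == 2], 2L)       # censored at 2
  expect_true(all(f$event_day <= 2L))

  # branch with no deaths is untouched
  rec0 <- makeRecords(rep(5L, 10L), rep("survived", 10L), tree_id = 2L,
                      group = "group10")
  expect_identical(firstAttackFilter(rec0), rec0)

  # simultaneous first-day deaths are all kept as events
  rec2 <- makeRecords(c(3L, 3L, rep(5L, 8L)),
                      c("died", "died", rep("survived", 8L)),
                      tree_id = 3L, group = "group10")
  f2 <- firstAttackFilter(rec2)
  expect_equal(sum(f2$event == "died"), 2L)

  # replacement individuals are excluded entirely
  rec3 <- rbind(rec,
                makeRecords(5L, "survived", tree_id = 1L, group = "group10",
                            replacement = TRUE, entry_day = 3L))
  f3 <- firstAttackFilter(rec3)
  expect_equal(nrow(f3), 10L)
  expect_false(any(f3$replacement))

  # keep_original_events only removes replacements
  f4 <- firstAttackFilter(rec3, rule = "keep_original_events")
  expect_equal(sum(f4$event == "died"), 2L)
  expect_equal(f4$event_day[f4$individual_id == 2], 4L)

  recBad <- rec; recBad$tree_id[1] <- NA
  expect_error(firstAttackFilter(recBad), "tree_id")
})

test_that("Cox engine: symmetric groups give a null coefficient", {
  # paired permutation fixture: both covariate groups share the same
  # event-time multiset
  tm <- c(1, 2, 3, 4, 5, 5, 1, 2, 3, 4, 5, 5)
  st <- c(1, 1, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0)
  x <- rep(c(0, 1), each = 6)
  fit <- coxPH(tm, st, cbind(x = x))
  expect_lt(abs(coef(fit)), 1e-6)
  expect_true(fit@converged)
})

test_that("Cox engine matches a brute-force partial-likelihood oracle on a toy set", {
  tm <- c(1, 1, 2, 3, 3, 4, 5, 5)
  st <- c(1, 0, 1, 1, 1, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0, 1, 0)
  fit <- coxPH(tm, st, cbind(x = x), ties = "efron")
  oracle <- optimize(function(b) efronLogLikOracle(b, tm, st, x),
                     c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(coef(fit)), oracle$maximum, tolerance = 1e-6)
  expect_equal(fit@loglik[2], oracle$objective, tolerance = 1e-10)
  expect_equal(unname(fit@hazardRatios), exp(unname(coef(fit))),
               tolerance = 1e-12)
})

test_that("Cox engine agrees with survival::coxph across ties and strata", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (rep in 1:5) {
    n <- 120
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
    str <- sample(1:2, n, replace = TRUE)
    tm <- sample(1:5, n, replace = TRUE)
    st <- rbinom(n, 1, 0.4)
    if (sum(st) < 2) next
    for (ties in c("efron", "breslow")) {
      ours <- coxPH(tm, st, cbind(a = x1, b = x2), strata = str, ties = ties)
      ref <- survival::coxph(survival::Surv(tm, st) ~ x1 + x2 +
                               survival::strata(str), ties = ties)
      expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-7)
      expect_equal(unname(ours@se),
                   unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    }
  }
})

test_that("Efron equals Breslow without ties; constant strata equal no strata", {
  set.seed(12)
  n <- 60
  tm <- sort(runif(n, 0, 10))  # continuous, no ties
  st <- rbinom(n, 1, 0.5); st[1] <- 1
  x <- rnorm(n)
  fe <- coxPH(tm, st, cbind(x = x), ties = "efron")
  fb <- coxPH(tm, st, cbind(x = x), ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-8)

  fs <- coxPH(tm, st, cbind(x = x), strata = rep(1L, n))
  expect_equal(coef(fs), coef(fe), tolerance = 1e-10)
})

test_that("complete separation of events is flagged, not silently reported", {
  tm <- c(1, 2, 3, 5, 5, 5)
  st <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)   # events only in x = 1
  expect_warning(fit <- coxPH(tm, st, cbind(x = x)), "converge")
  expect_false(fit@converged)
})

test_that("subset fits equal fits on manually subset records", {
  rec <- genPredation(seed = 44)
  f <- suppressMessages(firstAttackFilter(rec))
  grpFit <- coxFit(f, covariates = "color", subset = "group")
  manual <- coxFit(f[f$treatment_group == "group10", ],
                   covariates = "color")
  expect_equal(coef(grpFit), coef(manual))
  solFit <- coxFit(f, covariates = "color", subset = "solitary")
  manualS <- coxFit(f[f$treatment_group == "solitary", ],
                    covariates = "color")
  expect_equal(coef(solFit), coef(manualS))
  expect_equal(grpFit@nUsed, sum(f$treatment_group == "group10"))
})

test_that("mesh comparison recovers exposure effects and background equality", {
  # equal death proportions in mesh and exposed: coefficient near zero
  recEq <- rbind(
    makeRecords(rep(5L, 40), rep(c("died", "survived"), 20), tree_id = 1:40,
                exposed = "exposed", transect = rep(1:2, 20)),
    makeRecords(rep(5L, 40), rep(c("died", "survived"), 20), tree_id = 41:80,
                exposed = "mesh", transect = rep(1:2, 20)))
  m <- meshComparison(recEq)
  expect_lt(abs(coef(m$exposure)["exposed"]), 1e-4)

  # simulated 2% mesh vs ~30% exposed mortality: strong positive effect
  d <- experimentDesign(baselineHazard = 0.07, betaColor = 0, betaGroup = 0,
                        transectSD = 0)
  rec <- genPredation(d, seed = 9)
  m2 <- meshComparison(rec)
  expect_gt(coef(m2$exposure)["exposed"], 0)
  expect_lt(m2$exposure@p["exposed"], 0.05)
  # within mesh bags, colour and group have no systematic effect
  expect_true(all(m2$mesh_only@p[-1] > 0.01 | !m2$mesh_only@converged))
})

test_that("all-mesh-survive separation is reported with a warning note", {
  rec <- rbind(
    makeRecords(rep(5L, 30), rep(c("died", "survived", "survived"), 10),
                tree_id = 1:30, exposed = "exposed"),
    makeRecords(rep(5L, 30), rep("survived", 30), tree_id = 31:60,
                exposed = "mesh"))
  m <- meshComparison(rec)
  expect_gt(coef(m$exposure)["exposed"], 0)
  # mesh-only model has no deaths at all and must refuse to pretend
  expect_false(m$mesh_only@converged)
  expect_match(m$mesh_only@notes, "not estimable")
  expect_error(fitLogistic(rep(0, 10), cbind(1, rbinom(10, 1, 0.5))),
               "fewer than 2 distinct")
})
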