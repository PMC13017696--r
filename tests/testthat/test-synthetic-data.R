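test_that("spectrum recipes are deterministic, bounded and validated", {
  flat <- spectrumRecipe("flat", amplitude = 0.3)
  s <- genSpectrum(flat)
  expect_equal(specValues(s), rep(0.3, 451))
  expect_equal(range(wavelengths(s)), c(300, 750))

  noisy <- spectrumRecipe("gaussian_peak", amplitude = 0.5, peak = 550,
                          width = 40, noise_sd = 0.02, seed = 99)
  expect_identical(specValues(genSpectrum(noisy)),
                   specValues(genSpectrum(noisy)))  # same seed, same curve
  noisy2 <- noisy; noisy2$seed <- 100L
  expect_false(identical(specValues(genSpectrum(noisy)),
                         specValues(genSpectrum(noisy2))))
  expect_true(all(specValues(genSpectrum(noisy)) >= 0 &
                  specValues(genSpectrum(noisy)) <= 1))

  expect_error(spectrumRecipe("flat", amplitude = 1.2), "\\[0, 1\\]")
  # generators never disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(genSpectrum(noisy)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("preset ordering matches the intended conspicuousness structure", {
  vs <- bluetitVisualSystem()
  d65 <- illuminantD65()
  needles <- meanSpectrum(genSpectrumSet("needle_green", 6, 0.01, seed = 2))
  dorsal <- genSpectrum("larva_dorsal_green")
  ventral <- genSpectrum("larva_ventral_pale")

  # ventral (pale grey) shows more luminance contrast against needles
  expect_gt(deltaL(jndContrast(ventral, needles, vs, d65)),
            deltaL(jndContrast(dorsal, needles, vs, d65)))

  # yellow paint is chromatically conspicuous against the dorsum,
  # green paint is not (regression values computed with this vision model)
  dsYellow <- deltaS(jndContrast(genSpectrum("yellow_paint"), dorsal, vs,
                                 d65))
  dsGreen <- deltaS(jndContrast(genSpectrum("green_paint"), dorsal, vs,
                                d65))
  expect_gt(dsYellow, 3)
  expect_lt(dsGreen, 3)
  expect_equal(dsYellow, 18.191, tolerance = 1e-3)   # frozen regression
  expect_equal(dsGreen, 2.182, tolerance = 1e-3)
})

test_that("predation generator reproduces its own design", {
  d <- experimentDesign()
  rec <- genPredation(d, seed = 5)
  expect_identical(rec, genPredation(d, seed = 5))   # bit-reproducible
  expect_false(identical(rec, genPredation(d, seed = 6)))

  # branch bookkeeping: one branch per replicate, correct group sizes
  orig <- rec[!rec$replacement, ]
  expect_equal(length(unique(rec$tree_id)), sum(d$replicates))
  sizes <- table(orig$tree_id[orig$treatment_group == "group10"])
  expect_true(all(sizes == 10))
  expect_true(all(table(orig$tree_id[orig$treatment_group == "solitary"])
                  == 1))
  # replacements only on exposed branches, entering after day 0
  repl <- rec[rec$replacement, ]
  expect_true(all(repl$exposed == "exposed"))
  expect_true(all(repl$entry_day >= 1))
  expect_true(all(rec$event_day >= pmax(rec$entry_day, 1L)))

  # mesh mortality is low and unrelated to colour or group
  mesh <- rec[rec$exposed == "mesh", ]
  expect_true(all(mesh$event_day == 5L))
  expect_lt(mean(mesh$event == "died"), 0.15)
})

test_that("a null predation design yields equal death proportions across cells", {
  d <- experimentDesign(replicates = c(exposed_yellow_solitary = 150L,
                                       exposed_green_solitary = 150L),
                        betaColor = 0, betaGroup = 0, transectSD = 0,
                        replace = FALSE)
  rec <- do.call(rbind, lapply(1:10, function(i) genPredation(d, seed = i)))
  py <- mean(rec$event[rec$treatment_color == "yellow"] == "died")
  pg <- mean(rec$event[rec$treatment_color == "green"] == "died")
  n <- sum(rec$treatment_color == "yellow")
  expect_lt(abs(py - pg), 4 * sqrt(2 * 0.25 / n))  # binomial error bound
})

test_that("the generated colour hazard ratio is consistent with the design", {
  d <- experimentDesign(replicates = c(exposed_yellow_solitary = 200L,
                                       exposed_green_solitary = 200L),
                        betaColor = log(1.64), betaGroup = 0,
                        transectSD = 0, replace = FALSE)
  # empirical per-day discrete hazards aggregated over many replicates
  ev <- sapply(1:60, function(i) {
    r <- genPredation(d, seed = i)
    c(dy = sum(r$event == "died" & r$treatment_color == "yellow"),
      ny = sum(r$treatment_color == "yellow"),
      dg = sum(r$event == "died" & r$treatment_color == "green"),
      ng = sum(r$treatment_color == "green"))
  })
  tot <- rowSums(ev)
  # cumulative-hazard ratio over 5 days from survival fractions
  hrEmp <- log(1 - tot["dy"] / tot["ny"]) / log(1 - tot["dg"] / tot["ng"])
  expect_equal(unname(hrEmp), 1.64, tolerance = 0.08)
})

test_that("behaviour generator matches the family layout and its parameters", {
  b <- genBehavior(seed = 1)
  expect_equal(nrow(b), 51L)                      # default layout
  expect_equal(length(unique(b$family_id)), 12L)
  expect_true(all(table(b$family_id) %in% 3:5))
  expect_identical(b, genBehavior(seed = 1))
  for (i in 1:5) {
    bi <- genBehavior(nFamilies = 12L, seed = 100 + i)
    expect_true(nrow(bi) >= 36 && nrow(bi) <= 60)
  }
  expect_true(all(b$fluid_volume[b$fluid == "no"] == 0))
  expect_true(all(b$fluid_volume[b$fluid == "yes"] > 0))
  # contrasts live on the intended JND scale (lognormal around 4-8)
  expect_gt(median(b$ventral_color_jnd), 2)
  expect_lt(median(b$ventral_color_jnd), 12)
})

test_that("null behaviour generator yields slope CIs covering zero at the nominal rate", {
  pars <- list(uposture_intercept = 1.0, uposture_color_slope = 0,
               uposture_luminance_slope = 0, family_sd = 0)
  cover <- sapply(1:120, function(i) {
    b <- genBehavior(params = pars, seed = 500 + i)
    y <- as.integer(b$u_posture == "yes")
    x <- as.numeric(centerValues(b$ventral_luminance_jnd))
    f <- fitLogistic(y, cbind(`(Intercept)` = 1, lum = x))
    abs(coef(f)["lum"]) < 1.96 * f@se["lum"]
  })
  expect_gt(mean(cover), 0.9)
})

test_that("latent-scale intraclass correlation follows the logistic closed form", {
  # family SD 2, no slopes: ICC = sigma^2 / (sigma^2 + pi^2/3)
  pars <- list(uposture_intercept = 0, uposture_color_slope = 0,
               uposture_luminance_slope = 0, family_sd = 2)
  iccHat <- vapply(1:10, function(s) {
    b <- genBehavior(nFamilies = 40L, perFamily = rep(12L, 40),
                     params = pars, seed = 70 + s)
    y <- as.integer(b$u_posture == "yes")
    f <- fitLogistic(y, cbind(`(Intercept)` = rep(1, length(y))),
                     group = b$family_id)
    f@ranefSD^2 / (f@ranefSD^2 + pi^2 / 3)
  }, numeric(1))
  iccTrue <- 4 / (4 + pi^2 / 3)
  expect_lt(abs(mean(iccHat) - iccTrue), 0.1)
})

test_that("record CSV round-trips preserve both schemas", {
  rec <- genPredation(seed = 12)
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeSurvivalRecords(rec, p1)
  rec2 <- readSurvivalRecords(p1)
  expect_equal(rec2$event_day, rec$event_day)
  expect_equal(rec2$replacement, rec$replacement)

  b <- genBehavior(seed = 3)
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeBehaviorRecords(b, p2)
  b2 <- readBehaviorRecords(p2)
  expect_equal(b2$fluid_volume, b$fluid_volume, tolerance = 1e-12)
  expect_equal(b2$u_posture, b$u_posture)
})
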