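## Run code under a private RNG stream: seeds are threaded through the
## generators, never left in the global state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old))
      rm(".Random.seed", envir = globalenv())
    else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## ---- Synthetic spectra ------------------------------------------------------

#' Describe a synthetic reflectance spectrum
#'
#' A recipe is a deterministic description of a smooth reflectance curve:
#' a flat line, a Gaussian peak, a sigmoidal long-pass edge, or a mixture
#' (sum) of such components, plus optional additive Gaussian noise. All
#' amplitudes are reflectance fractions in \[0, 1\]; generated curves are
#' clipped back into \[0, 1\] after noise.
#'
#' @param kind `"flat"`, `"gaussian_peak"`, `"sigmoid_edge"` or
#'   `"mixture"`.
#' @param amplitude peak amplitude (fraction, in \[0, 1\]).
#' @param base baseline reflectance added everywhere.
#' @param peak,width Gaussian centre and SD, nm.
#' @param edge,scale sigmoid midpoint and slope scale, nm.
#' @param components for `"mixture"`: list of recipes to sum.
#' @param noise_sd SD of additive Gaussian noise (default 0).
#' @param seed integer seed used when noise is drawn.
#' @param label label for the generated spectrum.
#' @return an object of class `"SpectrumRecipe"`.
#' @export
spectrumRecipe <- function(kind = c("flat", "gaussian_peak", "sigmoid_edge",
                                    "mixture"),
                           amplitude = 0.5, base = 0, peak = 550, width = 40,
                           edge = 500, scale = 15, components = NULL,
                           noise_sd = 0, seed = 1L, label = kind) {
  kind <- match.arg(kind)
  if (kind != "mixture") {
    if (!is.finite(amplitude) || amplitude < 0 || amplitude > 1)
      stop("amplitude must lie in [0, 1]")
    if (base < 0 || base > 1) stop("base must lie in [0, 1]")
  } else if (is.null(components) || !length(components)) {
    stop("a mixture recipe needs components")
  }
  structure(list(kind = kind, amplitude = amplitude, base = base,
                 peak = peak, width = width, edge = edge, scale = scale,
                 components = components, noise_sd = noise_sd,
                 seed = as.integer(seed), label = label),
            class = "SpectrumRecipe")
}

evalRecipe <- function(recipe, grid) {
  switch(recipe$kind,
    flat = rep(recipe$amplitude, length(grid)) + recipe$base,
    gaussian_peak = recipe$base +
      recipe$amplitude * exp(-(grid - recipe$peak)^2 / (2 * recipe$width^2)),
    sigmoid_edge = recipe$base +
      recipe$amplitude / (1 + exp(-(grid - recipe$edge) / recipe$scale)),
    mixture = Reduce(`+`, lapply(recipe$components, evalRecipe, grid = grid))
  )
}

#' Generate a synthetic reflectance spectrum
#'
#' Evaluates a [spectrumRecipe()] on a wavelength grid, adds seeded
#' Gaussian noise if requested, and clips into \[0, 1\]. Deterministic for
#' a fixed recipe seed.
#'
#' @param recipe a `"SpectrumRecipe"` (or a preset name accepted by
#'   [presetRecipe()]).
#' @param grid wavelength grid, default [canonicalGrid()].
#' @return a [Spectrum].
#' @export
genSpectrum <- function(recipe, grid = canonicalGrid()) {
  if (is.character(recipe)) recipe <- presetRecipe(recipe)
  stopifnot(inherits(recipe, "SpectrumRecipe"))
  v <- evalRecipe(recipe, grid)
  if (recipe$noise_sd > 0)
    v <- v + withSeed(recipe$seed, stats::rnorm(length(grid), 0,
                                                recipe$noise_sd))
  v <- pmin(pmax(v, 0), 1)
  new("Spectrum", wavelengths = as.numeric(grid), values = v,
      label = recipe$label, role = "reflectance",
      metadata = list(synthetic = TRUE, kind = recipe$kind))
}

#' Preset recipes for the study's stimulus classes
#'
#' Named stand-ins for the measured stimulus classes of the system: pine
#' needles (`needle_green`: dark green with a red edge), larval dorsal
#' coloration (`larva_dorsal_green`: a dimmer green), larval ventral side
#' (`larva_ventral_pale`: flat, brighter grey), yellow and green paint
#' patches, and the broadband pale defensive fluid. The presets are
#' ordered so that, under the default viewer, the ventral side has a higher
#' luminance contrast against needles than the dorsal side, the yellow
#' paint is clearly discriminable from the dorsum and the green paint is
#' not.
#'
#' @param name preset name, see above.
#' @param noise_sd,seed noise settings passed through to the recipe.
#' @return a `"SpectrumRecipe"`.
#' @export
presetRecipe <- function(name = c("needle_green", "larva_dorsal_green",
                                  "larva_ventral_pale", "yellow_paint",
                                  "green_paint", "defense_fluid"),
                         noise_sd = 0, seed = 1L) {
  name <- match.arg(name)
  mix <- function(..., label) spectrumRecipe("mixture",
    components = list(...), noise_sd = noise_sd, seed = seed, label = label)
  g <- function(amp, peak, width, base = 0)
    spectrumRecipe("gaussian_peak", amplitude = amp, peak = peak,
                   width = width, base = base)
  s <- function(amp, edge, scale, base = 0)
    spectrumRecipe("sigmoid_edge", amplitude = amp, edge = edge,
                   scale = scale, base = base)
  switch(name,
    needle_green = mix(g(0.08, 550, 40, base = 0.02), s(0.45, 710, 12),
                       label = "needle_green"),
    larva_dorsal_green = mix(g(0.06, 548, 42, base = 0.015), s(0.35, 715, 12),
                             label = "larva_dorsal_green"),
    larva_ventral_pale = spectrumRecipe("flat", amplitude = 0.25,
                                        noise_sd = noise_sd, seed = seed,
                                        label = "larva_ventral_pale"),
    yellow_paint = s(0.6, 505, 14, base = 0.04),
    green_paint = mix(g(0.07, 552, 42, base = 0.015), s(0.36, 714, 12),
                      label = "green_paint"),
    ## pale amber resin: broadband with a gentle long-wavelength rise
    defense_fluid = s(0.14, 530, 60, base = 0.13)
  ) -> r
  r$label <- name
  r$noise_sd <- noise_sd
  r$seed <- as.integer(seed)
  r
}

#' Generate a SpectrumSet of noisy replicates of one preset
#'
#' @param name preset name (see [presetRecipe()]).
#' @param n number of replicate spectra.
#' @param noise_sd additive noise SD per replicate.
#' @param seed integer; replicate `i` uses `seed + i`.
#' @param grid wavelength grid.
#' @return a [SpectrumSet].
#' @export
genSpectrumSet <- function(name, n = 3L, noise_sd = 0.01, seed = 1L,
                           grid = canonicalGrid()) {
  sp <- lapply(seq_len(n), function(i) {
    r <- presetRecipe(name, noise_sd = noise_sd, seed = seed + i)
    r$label <- sprintf("%s_%d", name, i)
    genSpectrum(r, grid)
  })
  SpectrumSet(sp, groupKey = name)
}

## ---- Predation experiment generator -----------------------------------------

#' Describe a field predation experiment
#'
#' The default design is the eight-cell layout of the motivating field
#' study: exposed and mesh-bag (predator-exclusion) branches crossed with
#' colour (cryptic green vs conspicuous yellow paint) and group size
#' (solitary vs group of 10), with replicate branch counts
#' 20/20/22/19 (exposed) and 9/10/10/9 (mesh), two transects, a five-day
#' horizon and daily checks with replacement of dead larvae.
#'
#' True effects are log hazard ratios on the daily predation hazard:
#' `betaColor` (yellow vs green) and `betaGroup` (group of 10 vs solitary),
#' plus a normal log-frailty per transect.
#'
#' @param replicates named integer vector of branch counts for the eight
#'   cells (names fixed, see default).
#' @param groupSize larvae per group branch (default 10).
#' @param horizonDays experiment length in days (default 5).
#' @param betaColor,betaGroup true log hazard ratios (defaults
#'   `log(1.64)` and `-0.429`).
#' @param transectSD SD of the per-transect log-frailty (default 0.25).
#' @param baselineHazard daily baseline hazard of a cryptic solitary larva
#'   (default 0.05).
#' @param meshMortality total background mortality probability inside a
#'   mesh bag over the whole experiment (default 0.02).
#' @param replace emit replacement larvae for killed originals
#'   (default `TRUE`).
#' @return a list of class `"ExperimentDesign"`.
#' @export
experimentDesign <- function(replicates = c(exposed_yellow_solitary = 20L,
                                            exposed_yellow_group = 20L,
                                            exposed_green_solitary = 22L,
                                            exposed_green_group = 19L,
                                            mesh_yellow_solitary = 9L,
                                            mesh_yellow_group = 10L,
                                            mesh_green_solitary = 10L,
                                            mesh_green_group = 9L),
                             groupSize = 10L, horizonDays = 5L,
                             betaColor = log(1.64), betaGroup = -0.429,
                             transectSD = 0.25, baselineHazard = 0.05,
                             meshMortality = 0.02, replace = TRUE) {
  if (any(replicates <= 0)) stop("replicate counts must be positive")
  if (horizonDays < 1L) stop("horizon must be at least one day")
  structure(list(replicates = replicates, groupSize = as.integer(groupSize),
                 horizonDays = as.integer(horizonDays),
                 betaColor = betaColor, betaGroup = betaGroup,
                 transectSD = transectSD, baselineHazard = baselineHazard,
                 meshMortality = meshMortality, replace = replace),
            class = "ExperimentDesign")
}

#' Simulate a field predation experiment
#'
#' Draws individual daily survival under a discrete-day proportional-
#' hazards model: each exposed larva dies on day `t` with probability
#' `1 - exp(-h0 * exp(betaColor * yellow + betaGroup * group + b_transect))`,
#' where `b_transect` is a normal log-frailty shared within transect.
#' Killed originals are (optionally) replaced the same day by replacement
#' larvae flagged `replacement = TRUE`, which may themselves die later --
#' exactly the exposure structure the [firstAttackFilter()] is designed to
#' undo. Mesh-bag larvae draw an independent end-of-experiment background
#' mortality unaffected by colour or group.
#'
#' @param design an [experimentDesign()].
#' @param seed integer seed (threaded; the global RNG state is restored).
#' @return data.frame of survival records with columns `individual_id`,
#'   `transect`, `tree_id`, `treatment_color`, `treatment_group`,
#'   `exposed`, `entry_day`, `event_day`, `event`, `replacement`.
#' @export
genPredation <- function(design = experimentDesign(), seed = 1L) {
  stopifnot(inherits(design, "ExperimentDesign"))
  withSeed(seed, {
    bTrans <- stats::rnorm(2L, 0, design$transectSD)
    H <- design$horizonDays
    acc <- list()
    tree0 <- 0L
    for (cell in names(design$replicates)) {
      parts <- strsplit(cell, "_", fixed = TRUE)[[1L]]
      exposedLab <- parts[1L]
      color <- parts[2L]
      grp <- if (parts[3L] == "group") "group10" else "solitary"
      nInd <- if (grp == "group10") design$groupSize else 1L
      nRep <- design$replicates[[cell]]
      treeIds <- tree0 + seq_len(nRep)
      tree0 <- tree0 + nRep
      transects <- ifelse(seq_len(nRep) %% 2L == 0L, 2L, 1L)

      if (exposedLab == "mesh") {
        tr <- rep(treeIds, each = nInd)
        tx <- rep(transects, each = nInd)
        n <- length(tr)
        died <- stats::runif(n) < design$meshMortality
        acc[[cell]] <- data.frame(
          transect = tx, tree_id = tr, treatment_color = color,
          treatment_group = grp, exposed = "mesh",
          entry_day = 0L, event_day = H,
          event = ifelse(died, "died", "survived"),
          replacement = FALSE, stringsAsFactors = FALSE)
        next
      }

      lp <- design$betaColor * (color == "yellow") +
        design$betaGroup * (grp == "group10") + bTrans
      pDay <- 1 - exp(-design$baselineHazard * exp(lp))  # per transect
      tr <- rep(treeIds, each = nInd)
      tx <- rep(transects, each = nInd)
      entry <- rep(0L, length(tr))
      repl <- rep(FALSE, length(tr))
      outTr <- outTx <- integer(0); outEntry <- outDay <- integer(0)
      outEvent <- character(0); outRepl <- logical(0)
      while (length(tr)) {
        ## geometric waiting time from the entry day (daily checks)
        wait <- stats::rgeom(length(tr), pDay[tx]) + 1L
        day <- entry + wait
        died <- day <= H
        day[!died] <- H
        outTr <- c(outTr, tr); outTx <- c(outTx, tx)
        outEntry <- c(outEntry, entry); outDay <- c(outDay, day)
        outEvent <- c(outEvent, ifelse(died, "died", "survived"))
        outRepl <- c(outRepl, repl)
        ## replacements enter on the death day, at risk the next day
        spawn <- design$replace & died & day < H
        tr <- tr[spawn]; tx <- tx[spawn]; entry <- day[spawn]
        repl <- rep(TRUE, sum(spawn))
      }
      acc[[cell]] <- data.frame(
        transect = outTx, tree_id = outTr, treatment_color = color,
        treatment_group = grp, exposed = "exposed",
        entry_day = outEntry, event_day = outDay, event = outEvent,
        replacement = outRepl, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, acc)
    out <- cbind(individual_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

## ---- Behaviour generator -----------------------------------------------------

#' Default parameters for the behaviour generator
#'
#' Generating values follow the reported scale of the system: logistic
#' intercepts near 1.2--1.7 (most larvae display), a negative colour-
#' contrast slope and positive luminance-contrast slope for the U-posture,
#' weak slopes for fluid deployment, a family random-intercept SD of 0.5,
#' and gamma-distributed fluid volumes (shape 2) whose log-mean rises
#' slowly with body length.
#'
#' @return named list of generator parameters; override any element via
#'   the `params` argument of [genBehavior()].
#' @export
behaviorParams <- function() {
  list(uposture_intercept = 1.7, uposture_color_slope = -0.433,
       uposture_luminance_slope = 0.289,
       fluid_intercept = 1.2, fluid_color_slope = -0.179,
       fluid_luminance_slope = 0.248,
       family_sd = 0.5,
       gamma_shape = 2, volume_intercept = 0.5,
       volume_color_slope = 0, volume_luminance_slope = 0,
       volume_length_slope = 0.05,
       color_meanlog = log(5), color_sdlog = 0.3,
       luminance_meanlog = log(6), luminance_sdlog = 0.35,
       length_mean = 22, length_sd = 2)
}

#' Simulate family-structured defensive-behaviour records
#'
#' Generates per-larva records with known ground truth: ventral/dorsal
#' colour and luminance contrasts drawn lognormal around 4--8 JND, binary
#' U-posture and fluid deployment from logistic models with shared family
#' random intercepts, and gamma-distributed fluid volumes (zero when no
#' fluid was produced) whose log-mean depends on centred contrast and body
#' length. The default family structure (12 families, per-family sizes a
#' permutation of 3/4/5 summing to 51) mirrors a realistic common-garden
#' phenotyping sample.
#'
#' @param nFamilies number of families (default 12).
#' @param perFamily integer vector of family sizes, recycled/permuted; by
#'   default a seeded permutation of sizes 3-5 totalling 51 individuals.
#' @param params generator parameters, see [behaviorParams()]; supply a
#'   partial list to override defaults.
#' @param seed integer seed (threaded).
#' @return data.frame of behaviour records (schema of
#'   `behaviorAnalysis()` input); attributes `"params"` carries the full
#'   generating parameter list.
#' @export
genBehavior <- function(nFamilies = 12L, perFamily = NULL,
                        params = list(), seed = 1L) {
  p <- utils::modifyList(behaviorParams(), params)
  withSeed(seed, {
    if (is.null(perFamily)) {
      ## default layout: 12 families with sizes 3-5 totalling 51
      perFamily <- if (nFamilies == 12L)
        sample(c(3L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 5L, 5L))
      else
        sample(3:5, nFamilies, replace = TRUE)
    }
    perFamily <- rep_len(perFamily, nFamilies)
    fam <- rep(seq_len(nFamilies), perFamily)
    n <- length(fam)
    vc <- stats::rlnorm(n, p$color_meanlog, p$color_sdlog)
    vl <- stats::rlnorm(n, p$luminance_meanlog, p$luminance_sdlog)
    dc <- stats::rlnorm(n, p$color_meanlog - 0.2, p$color_sdlog)
    dl <- stats::rlnorm(n, p$luminance_meanlog + 0.1, p$luminance_sdlog)
    len <- stats::rnorm(n, p$length_mean, p$length_sd)
    ## generator centres contrasts at their theoretical means so the
    ## intercepts match the centred-predictor models fitted downstream
    cvc <- vc - exp(p$color_meanlog + p$color_sdlog^2 / 2)
    cvl <- vl - exp(p$luminance_meanlog + p$luminance_sdlog^2 / 2)
    bU <- stats::rnorm(nFamilies, 0, p$family_sd)[fam]
    bF <- stats::rnorm(nFamilies, 0, p$family_sd)[fam]
    etaU <- p$uposture_intercept + p$uposture_color_slope * cvc +
      p$uposture_luminance_slope * cvl + bU
    etaF <- p$fluid_intercept + p$fluid_color_slope * cvc +
      p$fluid_luminance_slope * cvl + bF
    ## the two behaviours are drawn independently given family and
    ## contrast, keeping each model's generating parameters recoverable
    u <- stats::rbinom(n, 1L, stats::plogis(etaU))
    f <- stats::rbinom(n, 1L, stats::plogis(etaF))
    mu <- exp(p$volume_intercept + p$volume_color_slope * cvc +
              p$volume_luminance_slope * cvl +
              p$volume_length_slope * (len - p$length_mean))
    vol <- stats::rgamma(n, shape = p$gamma_shape,
                         scale = mu / p$gamma_shape)
    vol[f == 0L] <- 0
    out <- data.frame(
      individual_id = seq_len(n), family_id = fam, length_mm = len,
      u_posture = ifelse(u == 1L, "yes", "no"),
      fluid = ifelse(f == 1L, "yes", "no"),
      fluid_volume = vol,
      ventral_color_jnd = vc, ventral_luminance_jnd = vl,
      dorsal_color_jnd = dc, dorsal_luminance_jnd = dl)
    attr(out, "params") <- p
    out
  })
}
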