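#' Construct a VisualSystem
#'
#' @param sensitivities list of [Spectrum] objects (role `"sensitivity"`),
#'   one per single-cone channel, ordered short to long wavelength. Names
#'   of the list name the channels.
#' @param doubleCone [Spectrum]: double-cone sensitivity (achromatic
#'   channel).
#' @param abundances positive numeric, relative single-cone abundances in
#'   the same order.
#' @param weberRef Weber fraction of the most abundant single cone
#'   (default 0.05, the standard behavioural anchor for birds).
#' @param weberDouble Weber fraction of the double-cone channel
#'   (default 0.05).
#' @param name viewer label.
#' @return a [VisualSystem].
#' @export
VisualSystem <- function(sensitivities, doubleCone, abundances,
                         weberRef = 0.05, weberDouble = 0.05, name = "") {
  if (is.null(names(sensitivities)))
    names(sensitivities) <- paste0("cone", seq_along(sensitivities))
  new("VisualSystem", sensitivities = sensitivities, doubleCone = doubleCone,
      abundances = stats::setNames(as.numeric(abundances),
                                   names(sensitivities)),
      weberRef = weberRef, weberDouble = weberDouble,
      name = as.character(name))
}

setMethod("show", "VisualSystem", function(object) {
  cat(sprintf("VisualSystem '%s': %d single cones + double cone\n",
              object@name, length(object@sensitivities)))
  cat("  channels  :", paste(names(object@sensitivities), collapse = ", "),
      "\n")
  cat("  abundances:", paste(format(object@abundances), collapse = " : "),
      "\n")
  cat(sprintf("  Weber ref = %.3g (most abundant cone), double cone = %.3g\n",
              object@weberRef, object@weberDouble))
  invisible(object)
})

#' Visual pigment absorbance template
#'
#' Rhodopsin (A1) absorbance template of Govardovskii et al.: alpha band
#' plus beta band, parameterised only by the pigment's wavelength of peak
#' absorbance. Used to build receptor sensitivity curves when measured
#' whole-eye tables are not at hand.
#'
#' @param lambdaMax peak absorbance wavelength, nm.
#' @param grid wavelengths to evaluate, nm.
#' @return numeric absorbance, max-normalised to 1.
#' @export
pigmentTemplate <- function(lambdaMax, grid = canonicalGrid()) {
  x <- lambdaMax / grid
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax
  bb  <- -40.5 + 0.195 * lambdaMax
  beta <- 0.26 * exp(-((grid - lmb) / bb)^2)
  s <- alpha + beta
  s / max(s)
}

## Sigmoidal long-pass transmission used for simplified oil-droplet and
## ocular-media filtering (midpoint lambda50, slope scale in nm).
sigmoidTransmission <- function(grid, lambda50, scale) {
  1 / (1 + exp(-(grid - lambda50) / scale))
}

#' Synthetic blue tit visual system
#'
#' The packaged default viewer: a tetrachromatic passerine ("blue tit
#' type") built from pigment-template sensitivities rather than measured
#' tables. Single-cone peak absorbances are the blue tit values commonly
#' used in avian vision work (UVS 371, SWS 448, MWS 503, LWS 563 nm; the
#' double cone carries the LWS pigment), filtered by simplified sigmoidal
#' oil-droplet and ocular-media transmission. Relative cone abundances
#' default to UVS:SWS:MWS:LWS = 1 : 1.92 : 2.68 : 2.7, so the LWS cone is
#' most abundant and carries the reference Weber fraction of 0.05.
#'
#' These curves are a documented synthetic approximation: absolute JND
#' values depend on the exact sensitivity tables and abundance ratios, so
#' studies wanting to match a specific published viewer should load their
#' own tables with [loadVisualSystem()].
#'
#' @param grid wavelength grid, default [canonicalGrid()].
#' @param abundances relative single-cone abundances (UVS, SWS, MWS, LWS).
#' @param weberRef,weberDouble Weber fractions (defaults 0.05).
#' @return a [VisualSystem].
#' @export
bluetitVisualSystem <- function(grid = canonicalGrid(),
                                abundances = c(UVS = 1, SWS = 1.92,
                                               MWS = 2.68, LWS = 2.7),
                                weberRef = 0.05, weberDouble = 0.05) {
  peaks <- c(UVS = 371, SWS = 448, MWS = 503, LWS = 563)
  ## droplet long-pass midpoints (nm); UVS droplet is transparent
  droplet <- list(UVS = NULL, SWS = c(445, 12), MWS = c(505, 12),
                  LWS = c(560, 12))
  ocular <- sigmoidTransmission(grid, 322, 9)  # UV-absorbing media
  mk <- function(ch) {
    s <- pigmentTemplate(peaks[[ch]], grid) * ocular
    d <- droplet[[ch]]
    if (!is.null(d)) s <- s * sigmoidTransmission(grid, d[1L], d[2L])
    new("Spectrum", wavelengths = as.numeric(grid), values = s / max(s),
        label = paste0("bluetit_", ch), role = "sensitivity",
        metadata = list(synthetic = TRUE))
  }
  sens <- lapply(names(peaks), mk)
  names(sens) <- names(peaks)
  dbl_raw <- pigmentTemplate(563, grid) * ocular *
    sigmoidTransmission(grid, 420, 18)  # pale principal-cone droplet
  dbl <- new("Spectrum", wavelengths = as.numeric(grid),
             values = dbl_raw / max(dbl_raw), label = "bluetit_double",
             role = "sensitivity", metadata = list(synthetic = TRUE))
  VisualSystem(sens, dbl, abundances, weberRef, weberDouble,
               name = "bluetit_d65 (synthetic template curves)")
}

#' D65 daylight illuminant
#'
#' CIE D65 relative spectral power ("midday" daylight), interpolated onto
#' the requested grid from the packaged 10-nm table (300-750 nm,
#' normalised to 100 at 560 nm).
#'
#' @param grid wavelength grid, default [canonicalGrid()].
#' @return a [Spectrum] with role `"illuminant"`.
#' @export
illuminantD65 <- function(grid = canonicalGrid()) {
  path <- system.file("extdata", "illuminant_d65_10nm.csv",
                      package = "preyJND", mustWork = TRUE)
  s <- readSpectrum(path, dialect = "long_csv", role = "illuminant",
                    label = "D65")
  resampleSpectrum(s, grid)
}

#' Load a visual system from a descriptor directory
#'
#' A viewer directory contains a `descriptor.yaml` naming the channels and
#' numeric constants, plus a wide CSV of sensitivity curves:
#'
#' ```
#' name: my_viewer
#' sensitivities: sensitivities.csv   # wavelength_nm, <one column/channel>
#' single_cones: [UVS, SWS, MWS, LWS] # column names, short to long
#' double_cone: DBL                   # column name
#' abundances:  [1, 1.92, 2.68, 2.7]
#' weber_ref: 0.05
#' weber_double: 0.05
#' ```
#'
#' The packaged descriptor `"bluetit_d65"` resolves to the synthetic blue
#' tit viewer shipped with the package (see [bluetitVisualSystem()]).
#'
#' @param path directory containing `descriptor.yaml`, or the name of a
#'   packaged viewer.
#' @param grid wavelength grid the curves are resampled onto.
#' @return a [VisualSystem].
#' @export
loadVisualSystem <- function(path = "bluetit_d65", grid = canonicalGrid()) {
  if (!dir.exists(path)) {
    pkgdir <- system.file("extdata", path, package = "preyJND")
    if (!nzchar(pkgdir) || !dir.exists(pkgdir))
      stop("no viewer directory or packaged viewer named '", path, "'")
    path <- pkgdir
  }
  desc <- yaml::read_yaml(file.path(path, "descriptor.yaml"))
  set <- readSpectrumSet(file.path(path, desc$sensitivities),
                         role = "sensitivity")
  set <- resampleSpectrumSet(set, grid)
  labs <- vapply(set@spectra, specLabel, character(1))
  pick <- function(ch) {
    i <- match(ch, labs)
    if (is.na(i)) stop("sensitivity column '", ch, "' missing in ",
                       desc$sensitivities)
    set[[i]]
  }
  sens <- lapply(desc$single_cones, pick)
  names(sens) <- desc$single_cones
  VisualSystem(sens, pick(desc$double_cone),
               abundances = unlist(desc$abundances),
               weberRef = desc$weber_ref %||% 0.05,
               weberDouble = desc$weber_double %||% 0.05,
               name = desc$name %||% basename(path))
}
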