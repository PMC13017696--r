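#' @import methods
NULL

#' Spectrum: a wavelength-indexed curve
#'
#' A `Spectrum` holds one wavelength-indexed curve: a reflectance spectrum
#' of a stimulus, an illuminant spectral power distribution, or a receptor
#' spectral sensitivity. Wavelengths are in nanometres and must be strictly
#' increasing; values must be finite and, for reflectance, non-negative
#' (negative instrument readings are clipped at construction by the readers,
#' never silently turned into `NA`).
#'
#' @slot wavelengths numeric, strictly increasing, nm.
#' @slot values numeric, same length as `wavelengths`; reflectance fraction
#'   (dimensionless), relative spectral power, or relative sensitivity.
#' @slot label single character, free-text identifier.
#' @slot role one of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#' @slot metadata list of provenance notes (e.g. `clipped` count from
#'   import, `percent_rescaled` flag).
#'
#' @seealso [Spectrum()] for the user constructor, [readSpectrum()].
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavelengths = "numeric",
    values      = "numeric",
    label       = "character",
    role        = "character",
    metadata    = "list"
  ),
  prototype(label = "", role = "reflectance", metadata = list())
)

setValidity("Spectrum", function(object) {
  msg <- character()
  wl <- object@wavelengths
  v  <- object@values
  if (length(wl) < 2L) msg <- c(msg, "a Spectrum needs at least 2 samples")
  if (length(wl) != length(v))
    msg <- c(msg, "wavelengths and values differ in length")
  if (anyNA(wl) || any(!is.finite(wl)))
    msg <- c(msg, "wavelengths must be finite")
  if (length(wl) >= 2L && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (!object@role %in% c("reflectance", "illuminant", "sensitivity"))
    msg <- c(msg, "role must be 'reflectance', 'illuminant' or 'sensitivity'")
  if (identical(object@role, "reflectance") && length(v) && !anyNA(v) &&
      any(v < 0))
    msg <- c(msg, "reflectance values must be >= 0 (clip on import)")
  if (length(msg)) msg else TRUE
})

#' SpectrumSet: replicate spectra on one shared grid
#'
#' An ordered collection of [Spectrum] objects sharing an identical
#' wavelength grid, e.g. repeated needle measurements from several trees or
#' per-individual larval spectra. The shared grid is what makes pointwise
#' aggregation ([meanSpectrum()]) and channelwise cone-catch averaging
#' well defined.
#'
#' @slot spectra list of [Spectrum], all on one grid.
#' @slot groupKey single character describing the replicate structure
#'   ("tree", "individual", ...).
#'
#' @exportClass SpectrumSet
setClass("SpectrumSet",
  representation(spectra = "list", groupKey = "character"),
  prototype(groupKey = "")
)

setValidity("SpectrumSet", function(object) {
  sp <- object@spectra
  if (!length(sp)) return("SpectrumSet must contain at least one Spectrum")
  if (!all(vapply(sp, is, logical(1), class2 = "Spectrum")))
    return("all elements must be Spectrum objects")
  ref <- sp[[1L]]@wavelengths
  same <- vapply(sp, function(s)
    length(s@wavelengths) == length(ref) && all(s@wavelengths == ref),
    logical(1))
  if (!all(same)) return("all member spectra must share one wavelength grid")
  TRUE
})

#' VisualSystem: a receptor-noise-limited viewer
#'
#' Defines the viewer for the discriminability model: one spectral
#' sensitivity per single-cone channel (hue discrimination), a double-cone
#' sensitivity (luminance discrimination), relative cone abundances, and the
#' reference Weber fraction applied to the most abundant single cone. The
#' channel Weber fractions used by the chromatic model are derived from
#' these via [weberFractions()].
#'
#' @slot sensitivities list of [Spectrum] (role `"sensitivity"`), one per
#'   single-cone channel, ordered short to long wavelength
#'   (e.g. UVS, SWS, MWS, LWS).
#' @slot doubleCone [Spectrum], double-cone sensitivity.
#' @slot abundances positive numeric, relative abundance of each single
#'   cone, same order and length as `sensitivities`.
#' @slot weberRef numeric in (0, 1): Weber fraction of the most abundant
#'   single cone (0.05 for the packaged blue tit viewer).
#' @slot weberDouble numeric in (0, 1): Weber fraction of the double-cone
#'   (achromatic) channel.
#' @slot name single character.
#'
#' @seealso [bluetitVisualSystem()], [loadVisualSystem()]
#' @exportClass VisualSystem
setClass("VisualSystem",
  representation(
    sensitivities = "list",
    doubleCone    = "Spectrum",
    abundances    = "numeric",
    weberRef      = "numeric",
    weberDouble   = "numeric",
    name          = "character"
  ),
  prototype(name = "")
)

setValidity("VisualSystem", function(object) {
  msg <- character()
  ns <- length(object@sensitivities)
  if (ns < 2L) msg <- c(msg, "need at least 2 single-cone channels")
  if (!all(vapply(object@sensitivities, is, logical(1), class2 = "Spectrum")))
    msg <- c(msg, "sensitivities must be Spectrum objects")
  else {
    ref <- object@sensitivities[[1L]]@wavelengths
    ok <- vapply(object@sensitivities, function(s)
      length(s@wavelengths) == length(ref) && all(s@wavelengths == ref),
      logical(1))
    if (!all(ok) ||
        length(object@doubleCone@wavelengths) != length(ref) ||
        !all(object@doubleCone@wavelengths == ref))
      msg <- c(msg, "all sensitivities (incl. double cone) must share one grid")
    if (any(vapply(object@sensitivities, function(s) any(s@values < 0),
                   logical(1))))
      msg <- c(msg, "sensitivities must be non-negative")
  }
  if (length(object@abundances) != ns)
    msg <- c(msg, "one abundance per single-cone channel required")
  if (any(!is.finite(object@abundances)) || any(object@abundances <= 0))
    msg <- c(msg, "abundances must be strictly positive")
  for (w in c(ref = object@weberRef, dbl = object@weberDouble))
    if (!is.finite(w) || w <= 0 || w >= 1)
      msg <- c(msg, "Weber fractions must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' QuantumCatches: receptor photon catches for one stimulus
#'
#' Quantum catches of each single cone and of the double cone for one
#' stimulus under one illuminant, optionally von Kries normalised by the
#' catches of an adapting background (in which case the background itself
#' maps to all-ones).
#'
#' @slot single positive numeric, one catch per single-cone channel
#'   (named when the visual system names its channels).
#' @slot double positive numeric scalar, double-cone catch.
#' @slot normalized logical: `TRUE` once von Kries normalisation applied.
#' @slot stimulusLabel,backgroundLabel character labels for provenance.
#'
#' @exportClass QuantumCatches
setClass("QuantumCatches",
  representation(
    single          = "numeric",
    double          = "numeric",
    normalized      = "logical",
    stimulusLabel   = "character",
    backgroundLabel = "character"
  ),
  prototype(normalized = FALSE, stimulusLabel = "", backgroundLabel = "")
)

setValidity("QuantumCatches", function(object) {
  msg <- character()
  if (length(object@single) < 2L)
    msg <- c(msg, "need catches for at least 2 single-cone channels")
  if (any(!is.finite(object@single)) || any(object@single < 0))
    msg <- c(msg, "single-cone catches must be finite and non-negative")
  if (length(object@double) != 1L || !is.finite(object@double) ||
      object@double < 0)
    msg <- c(msg, "double-cone catch must be one finite non-negative number")
  if (length(msg)) msg else TRUE
})

#' ContrastResult: JND contrasts for one stimulus pair
#'
#' Chromatic (`deltaS`) and achromatic (`deltaL`) contrast between two
#' stimuli in just-noticeable-difference units, with the conventional
#' three-way discriminability classification of each: below 1 JND the pair
#' is likely indistinguishable, 1 to 3 JND distinguishable only under
#' optimal light, above 3 JND distinguishable.
#'
#' @slot deltaS non-negative numeric, chromatic JND.
#' @slot deltaL non-negative numeric, achromatic (luminance) JND.
#' @slot classS,classL character classification of each channel:
#'   `"indistinguishable"`, `"optimal_light_only"` or `"distinguishable"`.
#' @slot stimulusLabel,referenceLabel character labels.
#'
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(
    deltaS         = "numeric",
    deltaL         = "numeric",
    classS         = "character",
    classL         = "character",
    stimulusLabel  = "character",
    referenceLabel = "character"
  ),
  prototype(stimulusLabel = "", referenceLabel = "")
)

setValidity("ContrastResult", function(object) {
  msg <- character()
  if (!is.finite(object@deltaS) || object@deltaS < 0)
    msg <- c(msg, "deltaS must be finite and >= 0")
  if (!is.finite(object@deltaL) || object@deltaL < 0)
    msg <- c(msg, "deltaL must be finite and >= 0")
  cls <- c("indistinguishable", "optimal_light_only", "distinguishable")
  if (!object@classS %in% cls || !object@classL %in% cls)
    msg <- c(msg, "classS/classL must be a valid discriminability class")
  if (length(msg)) msg else TRUE
})

#' CoxFit: a fitted Cox proportional-hazards model
#'
#' Result of maximising the (optionally stratified) Cox partial likelihood
#' by damped Newton iteration. Coefficients are log hazard ratios;
#' `hazardRatios` is `exp(coefficients)` and standard errors come from the
#' observed information at the optimum.
#'
#' @slot coefficients named numeric, log hazard ratios.
#' @slot hazardRatios named numeric, `exp(coefficients)`.
#' @slot se,z,p named numeric: standard errors, Wald z, two-sided p.
#' @slot nUsed integer, records entering the fit; `nEvents` integer.
#' @slot tiesMethod `"efron"` or `"breslow"`.
#' @slot strata character: stratification note (`"none"` or the variable).
#' @slot loglik numeric length 2: partial log-likelihood at 0 and at
#'   the optimum.
#' @slot converged logical; `iterations` integer.
#'
#' @exportClass CoxFit
setClass("CoxFit",
  representation(
    coefficients = "numeric",
    hazardRatios = "numeric",
    se           = "numeric",
    z            = "numeric",
    p            = "numeric",
    nUsed        = "integer",
    nEvents      = "integer",
    tiesMethod   = "character",
    strata       = "character",
    loglik       = "numeric",
    converged    = "logical",
    iterations   = "integer"
  )
)

setValidity("CoxFit", function(object) {
  if (object@converged &&
      any(abs(object@hazardRatios - exp(object@coefficients)) >
          1e-12 * pmax(1, abs(object@hazardRatios))))
    return("hazardRatios must equal exp(coefficients)")
  TRUE
})

#' ModelFit: a fitted GLM or mixed-model summary
#'
#' Common container for the binomial GLM/GLMM and gamma log-link fits:
#' fixed-effect estimates with Wald inference, the random-intercept SD when
#' a grouping factor was used, and an honest convergence flag (no estimates
#' are reported for failed fits).
#'
#' @slot estimates,se,z,p named numeric per fixed-effect term.
#' @slot ranefSD numeric: random-intercept SD, `NA_real_` for plain GLMs.
#' @slot family,link character, e.g. `"binomial"`/`"logit"`.
#' @slot dispersion numeric: Pearson dispersion (gamma), 1 for binomial.
#' @slot n integer, observations used; `nGroups` integer (0 if ungrouped).
#' @slot converged logical.
#' @slot formula character description of the model fitted.
#' @slot notes character vector of fitting notes (fallbacks, separation
#'   warnings, boundary fits).
#'
#' @exportClass ModelFit
setClass("ModelFit",
  representation(
    estimates  = "numeric",
    se         = "numeric",
    z          = "numeric",
    p          = "numeric",
    ranefSD    = "numeric",
    family     = "character",
    link       = "character",
    dispersion = "numeric",
    n          = "integer",
    nGroups    = "integer",
    converged  = "logical",
    formula    = "character",
    notes      = "character"
  ),
  prototype(ranefSD = NA_real_, dispersion = 1, nGroups = 0L,
            notes = character())
)

setValidity("ModelFit", function(object) {
  ne <- length(object@estimates)
  if (length(object@se) != ne || length(object@z) != ne ||
      length(object@p) != ne)
    return("estimates, se, z and p must have matching lengths")
  if (object@converged && ne == 0L)
    return("a converged fit must report estimates")
  TRUE
})
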