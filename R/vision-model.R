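#' Quantum catch of one receptor
#'
#' Photon catch of a receptor viewing a stimulus under an illuminant:
#' the product of stimulus reflectance, receptor sensitivity and illuminant
#' spectral power, integrated over wavelength by the trapezoidal rule on
#' the shared grid.
#'
#' @param stimulus [Spectrum] (reflectance, or any radiance-like curve).
#' @param sensitivity [Spectrum], receptor spectral sensitivity.
#' @param illuminant [Spectrum], illuminant spectral power.
#' @return non-negative scalar; zero only for an identically zero integrand.
#' @export
quantumCatch <- function(stimulus, sensitivity, illuminant) {
  wl <- stimulus@wavelengths
  if (length(sensitivity@wavelengths) != length(wl) ||
      any(sensitivity@wavelengths != wl) ||
      length(illuminant@wavelengths) != length(wl) ||
      any(illuminant@wavelengths != wl))
    stop("stimulus, sensitivity and illuminant must share one grid ",
         "(resampleSpectrum() first)")
  pracma::trapz(wl, stimulus@values * sensitivity@values * illuminant@values)
}

#' Cone quantum catches of a stimulus for a viewer
#'
#' Computes the quantum catch of every single cone and of the double cone
#' for one stimulus under one illuminant. When an adapting `background`
#' spectrum is supplied, each channel's catch is divided by that channel's
#' catch of the background (von Kries chromatic adaptation), so the
#' background itself maps to all-ones and any rescaling of the illuminant
#' cancels exactly.
#'
#' @param stimulus [Spectrum].
#' @param vs [VisualSystem].
#' @param illuminant [Spectrum].
#' @param background optional [Spectrum]; `NULL` for raw catches.
#' @return a [QuantumCatches] object.
#' @export
catchVector <- function(stimulus, vs, illuminant, background = NULL) {
  q <- vapply(vs@sensitivities, quantumCatch, numeric(1),
              stimulus = stimulus, illuminant = illuminant)
  qd <- quantumCatch(stimulus, vs@doubleCone, illuminant)
  bglab <- ""
  if (!is.null(background)) {
    qb <- vapply(vs@sensitivities, quantumCatch, numeric(1),
                 stimulus = background, illuminant = illuminant)
    qbd <- quantumCatch(background, vs@doubleCone, illuminant)
    if (any(qb == 0) || qbd == 0)
      stop("degenerate adapting background: zero catch in some channel")
    q <- q / qb
    qd <- qd / qbd
    bglab <- background@label
  }
  new("QuantumCatches", single = q, double = qd,
      normalized = !is.null(background),
      stimulusLabel = stimulus@label, backgroundLabel = bglab)
}

#' Channel Weber fractions from cone abundances
#'
#' Receptor noise in the discriminability model scales with the reciprocal
#' square root of cone abundance: the most abundant cone is assigned the
#' reference Weber fraction exactly, and every other channel gets
#' `weberRef * sqrt(max(abundances) / abundance)`, hence a Weber fraction
#' at least as large.
#'
#' @param vs a [VisualSystem], or a positive numeric abundance vector.
#' @param weberRef reference Weber fraction; taken from `vs` when a
#'   [VisualSystem] is given.
#' @return numeric vector of channel Weber fractions.
#' @export
weberFractions <- function(vs, weberRef = 0.05) {
  if (is(vs, "VisualSystem")) {
    eta <- vs@abundances
    weberRef <- vs@weberRef
  } else {
    eta <- as.numeric(vs)
    if (any(!is.finite(eta)) || any(eta <= 0))
      stop("abundances must be strictly positive")
  }
  weberRef * sqrt(max(eta) / eta)
}

logCatchDiff <- function(a, b) {
  qa <- if (is(a, "QuantumCatches")) a@single else as.numeric(a)
  qb <- if (is(b, "QuantumCatches")) b@single else as.numeric(b)
  if (length(qa) != length(qb))
    stop("catch vectors have different channel counts")
  if (any(qa <= 0) || any(qb <= 0))
    stop("quantum catches must be strictly positive for log receptor signals")
  log(qa) - log(qb)
}

#' Chromatic contrast in JND units
#'
#' Receptor-noise-limited chromatic distance between two stimuli. Receptor
#' signals are logarithmic (Fechner) catch ratios, `df_i = ln(Qa_i/Qb_i)`;
#' the contrast is the noise-weighted distance between the signal vectors
#' in the subspace orthogonal to the achromatic direction. For two
#' channels this is the familiar closed form
#' `|df1 - df2| / sqrt(w1^2 + w2^2)`; for three or more channels the
#' pairwise form
#' `dS^2 = sum_{i<j} (df_i - df_j)^2/(w_i w_j)^2 / sum_i 1/w_i^2`
#' is used, which reduces to the standard published trichromat and
#' tetrachromat formulas.
#'
#' @param a,b [QuantumCatches] (or bare positive catch vectors), matching
#'   channel counts. When von Kries normalisation is wanted it must already
#'   have been applied by [catchVector()].
#' @param weber numeric vector of channel Weber fractions
#'   (see [weberFractions()]).
#' @return non-negative scalar `dS` in JND; symmetric in `a` and `b`, zero
#'   iff the catch vectors are proportional along the achromatic axis.
#' @export
chromaticJND <- function(a, b, weber) {
  df <- logCatchDiff(a, b)
  w <- as.numeric(weber)
  if (length(w) != length(df))
    stop("need one Weber fraction per channel")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("Weber fractions must be positive")
  n <- length(df)
  if (n == 2L)
    return(abs(df[1L] - df[2L]) / sqrt(w[1L]^2 + w[2L]^2))
  ij <- utils::combn(n, 2L)
  num <- sum((df[ij[1L, ]] - df[ij[2L, ]])^2 /
             (w[ij[1L, ]]^2 * w[ij[2L, ]]^2))
  den <- sum(1 / w^2)
  sqrt(num / den)
}

#' Achromatic (luminance) contrast in JND units
#'
#' Double-cone contrast `dL = |ln(QDa / QDb)| / weberDouble`.
#'
#' @param a,b [QuantumCatches] (or positive scalar double-cone catches).
#' @param weberDouble Weber fraction of the double-cone channel.
#' @return non-negative scalar `dL` in JND, symmetric in `a` and `b`.
#' @export
achromaticJND <- function(a, b, weberDouble = 0.05) {
  qa <- if (is(a, "QuantumCatches")) a@double else as.numeric(a)
  qb <- if (is(b, "QuantumCatches")) b@double else as.numeric(b)
  if (qa <= 0 || qb <= 0)
    stop("double-cone catches must be strictly positive")
  if (weberDouble <= 0) stop("weberDouble must be positive")
  abs(log(qa / qb)) / weberDouble
}

#' Classify a JND value
#'
#' The conventional three-way reading of receptor-noise-limited contrasts:
#' below 1 JND two objects are likely indistinguishable; from 1 to 3 JND
#' (inclusive at both ends) likely distinguishable only under optimal light
#' conditions; above 3 JND likely distinguishable.
#'
#' @param jnd non-negative numeric (vectorised).
#' @return character vector in `{"indistinguishable", "optimal_light_only",
#'   "distinguishable"}`.
#' @export
classifyJND <- function(jnd) {
  jnd <- as.numeric(jnd)
  if (any(!is.finite(jnd)) || any(jnd < 0))
    stop("JND values must be finite and >= 0")
  out <- character(length(jnd))
  out[jnd < 1] <- "indistinguishable"
  out[jnd >= 1 & jnd <= 3] <- "optimal_light_only"
  out[jnd > 3] <- "distinguishable"
  out
}

#' Full JND contrast between two stimuli
#'
#' Convenience wrapper: computes von Kries-normalised catch vectors for the
#' two stimuli (adapting background defaults to the illuminant itself, i.e.
#' an ideal white), then chromatic and achromatic JND with classification.
#'
#' @param stimulus,reference [Spectrum] objects on the viewer's grid.
#' @param vs [VisualSystem].
#' @param illuminant [Spectrum].
#' @param background adapting background [Spectrum]; `NULL` (default) uses
#'   the illuminant itself.
#' @return a [ContrastResult].
#' @export
jndContrast <- function(stimulus, reference, vs, illuminant,
                        background = NULL) {
  if (is.null(background)) {
    background <- new("Spectrum", wavelengths = illuminant@wavelengths,
                      values = rep(1, length(illuminant@wavelengths)),
                      label = "ideal white", role = "reflectance")
  }
  qa <- catchVector(stimulus, vs, illuminant, background)
  qb <- catchVector(reference, vs, illuminant, background)
  contrastFromCatches(qa, qb, vs)
}

## dS/dL + classification from two ready catch vectors.
contrastFromCatches <- function(qa, qb, vs) {
  ds <- chromaticJND(qa, qb, weberFractions(vs))
  dl <- achromaticJND(qa, qb, vs@weberDouble)
  new("ContrastResult", deltaS = ds, deltaL = dl,
      classS = classifyJND(ds), classL = classifyJND(dl),
      stimulusLabel = qa@stimulusLabel, referenceLabel = qb@stimulusLabel)
}
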