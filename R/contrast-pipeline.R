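#' Paint-patch conspicuousness verification
#'
#' Verifies how a paint treatment changes a stimulus for the modelled
#' viewer: computes a catch vector per spectrum in each set, averages the
#' catches channelwise within each set, and returns one chromatic /
#' achromatic JND contrast between the two mean catch vectors. Note the
#' deliberate order of operations -- mean of catches, not catch of the mean
#' spectrum -- which is the convention for paint verification, whereas
#' natural backgrounds are averaged as spectra first (see
#' [buildContrastTable()]).
#'
#' @param painted,unpainted [SpectrumSet]s (at least one spectrum each).
#' @param vs [VisualSystem].
#' @param illuminant [Spectrum].
#' @param background adapting background [Spectrum] for von Kries
#'   normalisation; `NULL` uses the illuminant (ideal white).
#' @return a [ContrastResult].
#' @export
paintVerification <- function(painted, unpainted, vs, illuminant,
                              background = NULL) {
  stopifnot(is(painted, "SpectrumSet"), is(unpainted, "SpectrumSet"))
  meanCatch <- function(set, lab) {
    qs <- lapply(set@spectra, catchVector, vs = vs, illuminant = illuminant,
                 background = background)
    new("QuantumCatches",
        single = rowMeans(vapply(qs, catchSingle,
                                 numeric(length(vs@sensitivities)))),
        double = mean(vapply(qs, catchDouble, numeric(1))),
        normalized = qs[[1L]]@normalized,
        stimulusLabel = lab,
        backgroundLabel = qs[[1L]]@backgroundLabel)
  }
  qa <- meanCatch(painted,
                  paste0("mean(", specLabel(painted[[1L]]), "...)"))
  qb <- meanCatch(unpainted,
                  paste0("mean(", specLabel(unpainted[[1L]]), "...)"))
  contrastFromCatches(qa, qb, vs)
}

#' Build a table of stimulus contrasts against a natural background
#'
#' Reproduces the standard comparison battery for a set of named stimuli
#' (e.g. `dorsal`, `ventral`, `fluid`, paint patches) against a background
#' set (e.g. pine needles): every stimulus is contrasted against the
#' pointwise *mean background spectrum*, and when a `fluid` stimulus is
#' present the fluid is additionally contrasted against the dorsal and
#' ventral stimuli themselves.
#'
#' Two row types are produced and never conflated:
#' * `per_individual = TRUE`: one row per member spectrum of each stimulus
#'   set against the mean background (row type `"individual"`), the format
#'   consumed by the behaviour--colour models;
#' * `per_individual = FALSE`: one row per stimulus set using channelwise
#'   mean catches (row type `"mean_catch"`).
#'
#' Fluid-vs-larva rows always use mean catches, since defensive fluid is
#' typically measured as a pooled sample.
#'
#' @param stimuli named list of [SpectrumSet]s; recognised special names
#'   are `"fluid"`, `"dorsal"`, `"ventral"` (any other names are contrasted
#'   against the background only).
#' @param background [SpectrumSet] of background spectra (e.g. needles).
#' @param vs [VisualSystem]; @param illuminant [Spectrum].
#' @param perIndividual logical, see above.
#' @param vkBackground adapting background for von Kries normalisation:
#'   `"white"` (the illuminant itself, default) or `"background"` (the mean
#'   background spectrum).
#' @return a `data.frame` with columns `stimulus_label`, `reference_label`,
#'   `delta_s`, `delta_l`, `class_s`, `class_l`, `n_spectra_averaged`,
#'   `row_type`.
#' @export
buildContrastTable <- function(stimuli, background, vs, illuminant,
                               perIndividual = FALSE,
                               vkBackground = c("white", "background")) {
  vkBackground <- match.arg(vkBackground)
  stopifnot(is(background, "SpectrumSet"))
  if (is.null(names(stimuli)) || any(!nzchar(names(stimuli))))
    stop("stimuli must be a fully named list of SpectrumSet objects")
  if (!all(vapply(stimuli, is, logical(1), class2 = "SpectrumSet")))
    stop("each stimulus must be a SpectrumSet")

  bgMean <- meanSpectrum(background, label = "background")
  adapt <- if (vkBackground == "background") bgMean else NULL

  qOf <- function(s) catchVector(s, vs, illuminant, adapt)
  if (is.null(adapt)) {
    white <- new("Spectrum", wavelengths = illuminant@wavelengths,
                 values = rep(1, length(illuminant@wavelengths)),
                 label = "ideal white", role = "reflectance")
    qOf <- function(s) catchVector(s, vs, illuminant, white)
  }
  meanQ <- function(set, lab) {
    qs <- lapply(set@spectra, qOf)
    new("QuantumCatches",
        single = rowMeans(vapply(qs, catchSingle,
                                 numeric(length(vs@sensitivities)))),
        double = mean(vapply(qs, catchDouble, numeric(1))),
        normalized = TRUE, stimulusLabel = lab,
        backgroundLabel = qs[[1L]]@backgroundLabel)
  }

  qBg <- qOf(bgMean)
  rows <- list()
  addRow <- function(stimLab, refLab, qa, qb, nAvg, type) {
    cr <- contrastFromCatches(qa, qb, vs)
    rows[[length(rows) + 1L]] <<- data.frame(
      stimulus_label = stimLab, reference_label = refLab,
      delta_s = cr@deltaS, delta_l = cr@deltaL,
      class_s = cr@classS, class_l = cr@classL,
      n_spectra_averaged = nAvg, row_type = type,
      stringsAsFactors = FALSE)
  }

  for (nm in names(stimuli)) {
    set <- stimuli[[nm]]
    if (perIndividual) {
      for (i in seq_along(set@spectra)) {
        s <- set[[i]]
        lab <- if (nzchar(specLabel(s))) specLabel(s)
               else sprintf("%s_%d", nm, i)
        addRow(lab, "background(mean)", qOf(s), qBg, 1L, "individual")
      }
    } else {
      addRow(nm, "background(mean)",
             meanQ(set, nm), qBg, length(set@spectra), "mean_catch")
    }
  }

  if ("fluid" %in% names(stimuli)) {
    qFluid <- meanQ(stimuli[["fluid"]], "fluid")
    for (ref in intersect(c("dorsal", "ventral"), names(stimuli))) {
      addRow("fluid", ref, qFluid,
             meanQ(stimuli[[ref]], ref),
             length(stimuli[["fluid"]]@spectra), "mean_catch")
    }
    if (perIndividual)  # mean-catch fluid-vs-needles row is then missing
      addRow("fluid", "background(mean)", qFluid, qBg,
             length(stimuli[["fluid"]]@spectra), "mean_catch")
  }
  do.call(rbind, rows)
}
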