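#' Construct a Spectrum
#'
#' User-facing constructor. Wavelengths are sorted if needed (duplicates are
#' an error), and for `role = "reflectance"` negative values are clipped to
#' zero with the clip count recorded in the metadata -- the convention for
#' spectrophotometer exports, where small negative readings are instrument
#' noise.
#'
#' @param wavelengths numeric vector, nm.
#' @param values numeric vector, same length.
#' @param label free-text label.
#' @param role `"reflectance"` (default), `"illuminant"` or `"sensitivity"`.
#' @param metadata list of provenance notes.
#' @return a [Spectrum] object.
#' @examples
#' s <- Spectrum(300:750, rep(0.2, 451), label = "flat grey")
#' head(wavelengths(s))
#' @export
Spectrum <- function(wavelengths, values, label = "",
                     role = c("reflectance", "illuminant", "sensitivity"),
                     metadata = list()) {
  role <- match.arg(role)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values differ in length")
  if (is.unsorted(wavelengths, strictly = FALSE)) {
    o <- order(wavelengths)
    wavelengths <- wavelengths[o]
    values <- values[o]
  }
  if (anyDuplicated(wavelengths))
    stop("duplicate wavelengths; aggregate or decimate before construction")
  if (role == "reflectance" && any(values < 0, na.rm = TRUE)) {
    nclip <- sum(values < 0, na.rm = TRUE)
    values <- pmax(values, 0)
    metadata$clipped <- (metadata$clipped %||% 0L) + nclip
    warning(sprintf("clipped %d negative reflectance value(s) to 0", nclip))
  }
  new("Spectrum", wavelengths = wavelengths, values = values,
      label = as.character(label), role = role, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a SpectrumSet
#'
#' @param spectra a list of [Spectrum] objects (or several spectra passed
#'   via `...`), all on one shared wavelength grid.
#' @param groupKey label for the replicate structure, e.g. `"tree"`.
#' @return a [SpectrumSet].
#' @export
SpectrumSet <- function(spectra, groupKey = "") {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  new("SpectrumSet", spectra = spectra, groupKey = as.character(groupKey))
}

#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("specValues", "Spectrum", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("specLabel", "Spectrum", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("specRole", "Spectrum", function(x) x@role)

#' @rdname accessors
#' @export
setMethod("specMetadata", "Spectrum", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectrumSet",
          function(x) x@spectra[[1L]]@wavelengths)

#' @rdname accessors
#' @export
setMethod("nSpectra", "SpectrumSet", function(x) length(x@spectra))

#' Extract one member of a SpectrumSet
#' @param x a [SpectrumSet]; @param i index.
#' @return a [Spectrum].
#' @rdname SpectrumSet-extract
#' @aliases [[,SpectrumSet-method
#' @export
setMethod("[[", "SpectrumSet", function(x, i) x@spectra[[i]])

#' Number of spectra in a set
#' @param x a [SpectrumSet].
#' @export
setMethod("length", "SpectrumSet", function(x) length(x@spectra))

setMethod("show", "Spectrum", function(object) {
  wl <- object@wavelengths
  cat(sprintf("Spectrum '%s' [%s]: %d samples, %.5g-%.5g nm, values %.4g-%.4g\n",
              object@label, object@role, length(wl), min(wl), max(wl),
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet (%s): %d spectra on %d-point grid %.5g-%.5g nm\n",
              if (nzchar(object@groupKey)) object@groupKey else "ungrouped",
              length(object@spectra),
              length(wavelengths(object)),
              min(wavelengths(object)), max(wavelengths(object))))
  invisible(object)
})

setMethod("show", "QuantumCatches", function(object) {
  cat(sprintf("QuantumCatches for '%s'%s (%s):\n", object@stimulusLabel,
              if (nzchar(object@backgroundLabel))
                paste0(" vs background '", object@backgroundLabel, "'") else "",
              if (object@normalized) "von Kries normalised" else "raw"))
  print(c(object@single, double = unname(object@double)))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("catchSingle", "QuantumCatches", function(x) x@single)

#' @rdname accessors
#' @export
setMethod("catchDouble", "QuantumCatches", function(x) x@double)

#' @rdname accessors
#' @export
setMethod("deltaS", "ContrastResult", function(x) x@deltaS)

#' @rdname accessors
#' @export
setMethod("deltaL", "ContrastResult", function(x) x@deltaL)

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("Contrast '%s' vs '%s':\n  chromatic  dS = %.3f JND (%s)\n  achromatic dL = %.3f JND (%s)\n",
              object@stimulusLabel, object@referenceLabel,
              object@deltaS, object@classS, object@deltaL, object@classL))
  invisible(object)
})

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("Cox proportional-hazards fit (%s ties, strata: %s)\n",
              object@tiesMethod, object@strata))
  cat(sprintf("n = %d, events = %d, converged: %s (%d iterations)\n",
              object@nUsed, object@nEvents, object@converged,
              object@iterations))
  if (length(object@coefficients)) {
    tab <- data.frame(
      coef = object@coefficients, `hazard ratio` = object@hazardRatios,
      se = object@se, z = object@z, p = object@p, check.names = FALSE)
    print(round(tab, 4))
  }
  invisible(object)
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("%s model (%s link)%s: %s\n", object@family, object@link,
              if (object@nGroups > 0L)
                sprintf(", %d groups", object@nGroups) else "",
              object@formula))
  cat(sprintf("n = %d, converged: %s\n", object@n, object@converged))
  if (length(object@estimates)) {
    tab <- data.frame(estimate = object@estimates, se = object@se,
                      z = object@z, p = object@p)
    print(round(tab, 4))
  }
  if (!is.na(object@ranefSD))
    cat(sprintf("random-intercept SD = %.4f\n", object@ranefSD))
  if (object@family == "gamma")
    cat(sprintf("Pearson dispersion = %.4f\n", object@dispersion))
  for (nt in object@notes) cat("note:", nt, "\n")
  invisible(object)
})

#' Coefficients of fitted models
#' @param object a [CoxFit] or [ModelFit].
#' @param ... ignored.
#' @return named numeric vector of estimates (log hazard ratios for Cox).
#' @export
setMethod("coef", "CoxFit", function(object, ...) object@coefficients)

#' @rdname coef-CoxFit-method
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@estimates)
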