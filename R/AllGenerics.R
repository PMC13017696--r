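#' Accessors for spectral and model classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `wavelengths()` / `specValues()` / `specLabel()` / `specRole()` for
#' [Spectrum], `nSpectra()` for [SpectrumSet], `deltaS()` / `deltaL()` for
#' [ContrastResult], and `catchSingle()` / `catchDouble()` for
#' [QuantumCatches].
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))

#' @rdname accessors
#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))

#' @rdname accessors
#' @export
setGeneric("specRole", function(x) standardGeneric("specRole"))

#' @rdname accessors
#' @export
setGeneric("specMetadata", function(x) standardGeneric("specMetadata"))

#' @rdname accessors
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' @rdname accessors
#' @export
setGeneric("deltaS", function(x) standardGeneric("deltaS"))

#' @rdname accessors
#' @export
setGeneric("deltaL", function(x) standardGeneric("deltaL"))

#' @rdname accessors
#' @export
setGeneric("catchSingle", function(x) standardGeneric("catchSingle"))

#' @rdname accessors
#' @export
setGeneric("catchDouble", function(x) standardGeneric("catchDouble"))
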