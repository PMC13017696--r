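#' Canonical wavelength grid
#'
#' All vision-model arithmetic in this package runs on an integer-nanometre
#' grid from 300 to 750 nm (451 points): the range covered by typical
#' field-spectrometer exports and by published 1-nm illuminant and cone
#' sensitivity tables.
#'
#' @return integer vector `300:750`.
#' @export
canonicalGrid <- function() 300:750

## Sniff the field separator of a delimited text file (comma or tab).
sniffSep <- function(path) {
  first <- readLines(path, n = 5L, warn = FALSE)
  first <- first[nzchar(first)]
  if (!length(first)) stop("empty spectrum file: ", path)
  if (sum(grepl("\t", first)) >= sum(grepl(",", first))) "\t" else ","
}

## Shared post-processing for raw wavelength/value columns: sort, decimate,
## percent auto-detection, negative clipping. Returns a validated Spectrum.
finishSpectrum <- function(wl, v, label, role, decimation, path = "<data>") {
  keep <- is.finite(wl)
  if (!all(keep)) {
    bad <- which(!keep)[1L]
    stop(sprintf("non-numeric wavelength on data row %d of %s", bad, path))
  }
  if (any(!is.finite(v)))
    stop(sprintf("non-numeric value on data row %d of %s",
                 which(!is.finite(v))[1L], path))
  o <- order(wl)
  wl <- wl[o]; v <- v[o]
  meta <- list()
  if (decimation == "first_per_nm") {
    bin <- floor(wl)
    first <- !duplicated(bin)
    wl <- wl[first]; v <- v[first]
  }
  if (anyDuplicated(wl))
    stop("non-increasing wavelengths after sort/decimation in ", path)
  ## percent-scale exports: reflectance far above 1 means percent units
  if (role == "reflectance" && max(v) > 1.5) {
    v <- v / 100
    meta$percent_rescaled <- TRUE
    message("values look like percent reflectance; divided by 100 (", path, ")")
  }
  if (role == "reflectance" && any(v < 0)) {
    meta$clipped <- sum(v < 0)
    v <- pmax(v, 0)
    warning(sprintf("clipped %d negative value(s) to 0 in %s",
                    meta$clipped, path))
  }
  new("Spectrum", wavelengths = wl, values = v, label = label, role = role,
      metadata = meta)
}

#' Read a reflectance (or other wavelength-indexed) spectrum
#'
#' Reads a two-column `wavelength,value` text file (`dialect = "long_csv"`)
#' or the first value column of a wide file (`dialect = "wide_csv"`: first
#' column wavelength, remaining columns one spectrum each, header row gives
#' labels). Comma- or tab-separated input is sniffed automatically.
#'
#' Spectrophotometer exports often sample several times per nanometre
#' (e.g. 0.47-nm steps); `decimation = "first_per_nm"` keeps only the first
#' sample in each integer-nanometre bin, the convention used when such
#' exports are reduced for vision modelling. Negative reflectance readings
#' are clipped to 0 (instrument noise) and the clip count stored in the
#' result metadata; percent-scale files (values well above 1) are divided by
#' 100 with a message.
#'
#' @param path file path.
#' @param dialect `"long_csv"` or `"wide_csv"`.
#' @param decimation `"none"` or `"first_per_nm"`.
#' @param label label for the result; defaults to the file name (long) or
#'   the column header (wide).
#' @param role spectrum role, default `"reflectance"`.
#' @return a [Spectrum].
#' @seealso [readSpectrumSet()] for all columns of a wide file,
#'   [writeSpectrum()] for the lossless inverse.
#' @export
readSpectrum <- function(path,
                         dialect = c("long_csv", "wide_csv"),
                         decimation = c("none", "first_per_nm"),
                         label = NULL,
                         role = "reflectance") {
  dialect <- match.arg(dialect)
  decimation <- match.arg(decimation)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniffSep(path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", comment.char = "",
                      fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(tab) < 2L) stop("need at least two columns in ", path)
  wl <- suppressWarnings(as.numeric(tab[[1L]]))
  if (any(is.na(wl)))
    stop(sprintf("non-numeric wavelength on data row %d of %s",
                 which(is.na(wl))[1L], path))
  col <- 2L
  v <- suppressWarnings(as.numeric(tab[[col]]))
  if (any(is.na(v)))
    stop(sprintf("non-numeric value on data row %d of %s",
                 which(is.na(v))[1L], path))
  if (is.null(label))
    label <- if (dialect == "wide_csv") names(tab)[col]
             else sub("\\.[^.]*$", "", basename(path))
  finishSpectrum(wl, v, label, role, decimation, path)
}

#' Read every spectrum column of a wide file as a SpectrumSet
#'
#' @inheritParams readSpectrum
#' @param groupKey replicate-structure label for the resulting set.
#' @return a [SpectrumSet] with one member per value column.
#' @export
readSpectrumSet <- function(path, decimation = c("none", "first_per_nm"),
                            groupKey = "", role = "reflectance") {
  decimation <- match.arg(decimation)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  wl <- suppressWarnings(as.numeric(tab[[1L]]))
  if (any(is.na(wl))) stop("non-numeric wavelengths in ", path)
  sp <- lapply(seq_len(ncol(tab) - 1L) + 1L, function(j) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column '%s' of %s",
                   names(tab)[j], path))
    finishSpectrum(wl, v, names(tab)[j], role, decimation, path)
  })
  SpectrumSet(sp, groupKey = groupKey)
}

#' Write a spectrum as long CSV
#'
#' Writes `wavelength_nm,value` with full precision, so that
#' [readSpectrum()] round-trips losslessly.
#'
#' @param s a [Spectrum].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "Spectrum"))
  df <- data.frame(wavelength_nm = format(s@wavelengths, digits = 17,
                                          trim = TRUE, scientific = FALSE),
                   value = format(s@values, digits = 17, trim = TRUE,
                                  scientific = FALSE))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a SpectrumSet as wide CSV
#'
#' First column `wavelength_nm`, one column per member spectrum, header row
#' carrying the member labels.
#'
#' @param set a [SpectrumSet]; @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectrumSet <- function(set, path) {
  stopifnot(is(set, "SpectrumSet"))
  cols <- lapply(set@spectra, function(s)
    format(s@values, digits = 17, trim = TRUE, scientific = FALSE))
  labs <- vapply(set@spectra, specLabel, character(1))
  labs[!nzchar(labs)] <- paste0("spectrum", seq_along(labs))[!nzchar(labs)]
  df <- data.frame(wavelength_nm = format(wavelengths(set), digits = 17,
                                          trim = TRUE, scientific = FALSE),
                   stats::setNames(cols, make.unique(labs)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`, which must lie within the support of
#' the source spectrum (no extrapolation). Used to put 0.47-nm spectrometer
#' data and 1-nm sensitivity/illuminant tables on one shared grid.
#'
#' @param s a [Spectrum].
#' @param grid target wavelengths (nm), within `range(wavelengths(s))`.
#' @param method only `"linear"`.
#' @return a [Spectrum] on `grid`.
#' @export
resampleSpectrum <- function(s, grid = canonicalGrid(), method = "linear") {
  stopifnot(is(s, "Spectrum"))
  method <- match.arg(method, "linear")
  grid <- as.numeric(grid)
  rng <- range(s@wavelengths)
  if (min(grid) < rng[1L] || max(grid) > rng[2L])
    stop(sprintf("target grid [%g, %g] outside source support [%g, %g]",
                 min(grid), max(grid), rng[1L], rng[2L]))
  v <- stats::approx(s@wavelengths, s@values, xout = grid,
                     method = "linear", ties = "ordered")$y
  new("Spectrum", wavelengths = grid, values = v, label = s@label,
      role = s@role, metadata = s@metadata)
}

#' Resample every member of a SpectrumSet
#'
#' @inheritParams resampleSpectrum
#' @param set a [SpectrumSet].
#' @return a [SpectrumSet] on `grid`.
#' @export
resampleSpectrumSet <- function(set, grid = canonicalGrid()) {
  SpectrumSet(lapply(set@spectra, resampleSpectrum, grid = grid),
              groupKey = set@groupKey)
}

#' Pointwise mean of a set of spectra
#'
#' Arithmetic mean at each wavelength across all members of the set -- the
#' convention for building a single background spectrum from replicate
#' measurements (e.g. needles from several trees).
#'
#' @param set a [SpectrumSet] (shared grid is enforced by the class).
#' @param label label for the result; default tags the input group key.
#' @return a [Spectrum].
#' @export
meanSpectrum <- function(set, label = NULL) {
  stopifnot(is(set, "SpectrumSet"))
  m <- rowMeans(vapply(set@spectra, specValues,
                       numeric(length(wavelengths(set)))))
  if (is.null(label))
    label <- sprintf("mean of %d spectra", length(set@spectra))
  new("Spectrum", wavelengths = wavelengths(set), values = m, label = label,
      role = set@spectra[[1L]]@role,
      metadata = list(n_averaged = length(set@spectra)))
}
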