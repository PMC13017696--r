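## ---- Behaviour records -----------------------------------------------------

behaviorCols <- c("individual_id", "family_id", "length_mm", "u_posture",
                  "fluid", "fluid_volume", "ventral_color_jnd",
                  "ventral_luminance_jnd", "dorsal_color_jnd",
                  "dorsal_luminance_jnd")

checkBehaviorRecords <- function(records, dropMales = TRUE) {
  miss <- setdiff(behaviorCols, names(records))
  if (length(miss))
    stop("behavior records are missing column(s): ",
         paste(miss, collapse = ", "))
  if ("sex" %in% names(records) && dropMales) {
    nmale <- sum(records$sex == "male", na.rm = TRUE)
    if (nmale > 0) {
      message("excluding ", nmale, " male record(s) from the analysis")
      records <- records[records$sex != "male", , drop = FALSE]
    }
  }
  if (any(records$fluid == "no" & records$fluid_volume != 0))
    stop("fluid = 'no' records must have fluid_volume 0 before ",
         "zero replacement")
  jnd <- c("ventral_color_jnd", "ventral_luminance_jnd",
           "dorsal_color_jnd", "dorsal_luminance_jnd")
  for (col in jnd)
    if (any(!is.finite(records[[col]])) || any(records[[col]] < 0))
      stop("contrast column ", col, " must be finite and non-negative")
  records
}

#' Centre a predictor
#'
#' Subtracts the arithmetic mean so the intercept of a downstream model
#' refers to an average-contrast individual. The centring constant is kept
#' as an attribute `"center"` for back-transformation.
#'
#' @param values numeric vector.
#' @return centred vector with attribute `"center"`.
#' @export
centerValues <- function(values) {
  if (!length(values)) stop("cannot centre an empty vector")
  m <- mean(values)
  structure(values - m, center = m)
}

#' Replace structural zeros before gamma modelling
#'
#' Gamma models require a strictly positive response, so zero fluid volumes
#' (individuals that produced no defensive fluid) are replaced by a small
#' positive constant, 0.001 by default.
#'
#' @param volumes non-negative numeric vector.
#' @param epsilon replacement value for exact zeros (default 0.001).
#' @return strictly positive vector; non-zero entries are untouched.
#' @export
replaceZeros <- function(volumes, epsilon = 0.001) {
  if (any(!is.finite(volumes)) || any(volumes < 0))
    stop("volumes must be finite and >= 0")
  volumes[volumes == 0] <- epsilon
  volumes
}

## ---- Model battery ---------------------------------------------------------

#' Behaviour--colour model battery
#'
#' Runs the standard battery linking defensive behaviour to coloration
#' contrasts on per-individual behaviour records:
#'
#' * `u_posture ~ ventral colour` and `~ ventral luminance` contrast,
#'   binomial GLMMs with a family random intercept;
#' * `fluid ~ ventral colour` and `~ ventral luminance` contrast, likewise;
#' * optionally the dorsal variants (`dorsal = TRUE`); the
#'   `u_posture ~ dorsal colour` model is fitted as a plain GLM, the one
#'   model of the battery conventionally run without the random intercept;
#' * `fluid_volume ~ contrast + length` gamma log-link GLMs (one per
#'   requested contrast), after zero replacement, with larval length always
#'   included to absorb allometry.
#'
#' All contrast predictors are centred internally; with fewer than two
#' families the mixed models fall back to GLMs with a note. If a `sex`
#' column is present, males are excluded up front.
#'
#' @param records behaviour record data.frame (see [genBehavior()] for the
#'   schema).
#' @param models subset of `c("uposture", "fluid", "volume")`.
#' @param dorsal also fit the dorsal-contrast variants of the binary
#'   models (default `FALSE`).
#' @param nodes quadrature nodes for the mixed fits.
#' @param epsilon zero-replacement constant for the volume models.
#' @return named list of [ModelFit]s, one per model of the battery.
#' @export
behaviorAnalysis <- function(records,
                             models = c("uposture", "fluid", "volume"),
                             dorsal = FALSE, nodes = 15L, epsilon = 0.001) {
  models <- match.arg(models, c("uposture", "fluid", "volume"),
                      several.ok = TRUE)
  records <- checkBehaviorRecords(records)
  fam <- records$family_id
  out <- list()

  binModel <- function(yesno, contrastCol, label, mixed = TRUE) {
    y <- as.integer(yesno == "yes")
    x <- centerValues(records[[contrastCol]])
    X <- cbind(`(Intercept)` = 1, contrast = as.numeric(x))
    colnames(X)[2L] <- contrastCol
    fitLogistic(y, X, group = if (mixed) fam else NULL, nodes = nodes,
                formula = label)
  }

  if ("uposture" %in% models) {
    out$uposture_ventral_color <- binModel(
      records$u_posture, "ventral_color_jnd",
      "u_posture ~ ventral_color_jnd + (1 | family)")
    out$uposture_ventral_luminance <- binModel(
      records$u_posture, "ventral_luminance_jnd",
      "u_posture ~ ventral_luminance_jnd + (1 | family)")
    if (dorsal) {
      out$uposture_dorsal_color <- binModel(
        records$u_posture, "dorsal_color_jnd",
        "u_posture ~ dorsal_color_jnd (GLM)", mixed = FALSE)
      out$uposture_dorsal_luminance <- binModel(
        records$u_posture, "dorsal_luminance_jnd",
        "u_posture ~ dorsal_luminance_jnd + (1 | family)")
    }
  }
  if ("fluid" %in% models) {
    out$fluid_ventral_color <- binModel(
      records$fluid, "ventral_color_jnd",
      "fluid ~ ventral_color_jnd + (1 | family)")
    out$fluid_ventral_luminance <- binModel(
      records$fluid, "ventral_luminance_jnd",
      "fluid ~ ventral_luminance_jnd + (1 | family)")
    if (dorsal) {
      out$fluid_dorsal_color <- binModel(
        records$fluid, "dorsal_color_jnd",
        "fluid ~ dorsal_color_jnd + (1 | family)")
      out$fluid_dorsal_luminance <- binModel(
        records$fluid, "dorsal_luminance_jnd",
        "fluid ~ dorsal_luminance_jnd + (1 | family)")
    }
  }
  if ("volume" %in% models) {
    v <- replaceZeros(records$fluid_volume, epsilon)
    for (contrastCol in c("ventral_color_jnd", "ventral_luminance_jnd")) {
      x <- centerValues(records[[contrastCol]])
      X <- cbind(`(Intercept)` = 1, contrast = as.numeric(x),
                 length_mm = records$length_mm)
      colnames(X)[2L] <- contrastCol
      nm <- paste0("volume_", sub("_jnd$", "", contrastCol))
      out[[nm]] <- fitGammaLog(
        v, X, formula = paste0("fluid_volume ~ ", contrastCol,
                               " + length_mm (gamma, log link)"))
    }
  }
  out
}
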