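## ---- Survival records -----------------------------------------------------

survivalCols <- c("individual_id", "transect", "tree_id", "treatment_color",
                  "treatment_group", "exposed", "entry_day", "event_day",
                  "event", "replacement")

checkSurvivalRecords <- function(records) {
  miss <- setdiff(survivalCols, names(records))
  if (length(miss))
    stop("survival records are missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(is.na(records$tree_id)))
    stop("survival records must carry a tree_id (branch) for every row")
  if (any(!records$event %in% c("died", "survived")))
    stop("event must be 'died' or 'survived'")
  if (any(records$event_day < records$entry_day))
    stop("event_day must be >= entry_day")
  invisible(records)
}

#' First-attack filter for branch-level predation records
#'
#' Restricts daily predation records to the first attack on each
#' experimental branch, the filter applied before proportional-hazards
#' modelling when dead larvae are replaced during the experiment (a
#' replacement's exposure history differs from the original larvae).
#'
#' Replacement individuals are always removed. With the default rule
#' `"censor_at_first"`, each exposed branch is then truncated at its first
#' attack day: deaths on that day remain events, and every other original
#' individual on the branch is censored at that day. Branches never
#' attacked are untouched (their larvae stay censored at the experiment
#' horizon). The alternative rule `"keep_original_events"` only removes
#' replacements and keeps all original-larva events -- survival results are
#' typically insensitive to the choice.
#'
#' Mesh-bag (predator-exclusion) rows have no daily event granularity and
#' are dropped from the output with a message; analyse them with
#' [meshComparison()].
#'
#' @param records data.frame of survival records (see [genPredation()] for
#'   the schema).
#' @param rule `"censor_at_first"` (default) or `"keep_original_events"`.
#' @return a filtered data.frame of exposed, original-larva records.
#' @export
firstAttackFilter <- function(records,
                              rule = c("censor_at_first",
                                       "keep_original_events")) {
  rule <- match.arg(rule)
  checkSurvivalRecords(records)
  if (any(records$exposed == "mesh")) {
    message("dropping ", sum(records$exposed == "mesh"),
            " mesh-bag record(s); use meshComparison() for those")
    records <- records[records$exposed != "mesh", , drop = FALSE]
  }
  records <- records[!records$replacement, , drop = FALSE]
  if (rule == "keep_original_events") return(records)
  out <- lapply(split(records, records$tree_id), function(br) {
    died <- br$event == "died"
    if (!any(died)) return(br)
    d1 <- min(br$event_day[died])
    ## deaths on the first attack day stay events; everyone else on the
    ## branch (later deaths and survivors alike) leaves the risk set there
    br$event <- ifelse(died & br$event_day == d1, "died", "survived")
    br$event_day <- pmin(br$event_day, d1)
    br
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- Partial-likelihood engine --------------------------------------------

## Log partial likelihood, score and observed information for one stratum.
coxStratumQuantities <- function(beta, time, status, X, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[status == 1]))) {
    atRisk <- time >= t
    dead <- status == 1 & time == t
    d <- sum(dead)
    s0r <- sum(w[atRisk])
    s1r <- colSums(X[atRisk, , drop = FALSE] * w[atRisk])
    s2r <- crossprod(X[atRisk, , drop = FALSE] * sqrt(w[atRisk]))
    ll <- ll + sum(eta[dead])
    score <- score + colSums(X[dead, , drop = FALSE])
    if (ties == "breslow") {
      ll <- ll - d * log(s0r)
      score <- score - d * s1r / s0r
      info <- info + d * (s2r / s0r - tcrossprod(s1r / s0r))
    } else {  # efron
      s0d <- sum(w[dead])
      s1d <- colSums(X[dead, , drop = FALSE] * w[dead])
      s2d <- crossprod(X[dead, , drop = FALSE] * sqrt(w[dead]))
      for (l in seq_len(d) - 1L) {
        f <- l / d
        s0 <- s0r - f * s0d
        s1 <- s1r - f * s1d
        s2 <- s2r - f * s2d
        ll <- ll - log(s0)
        score <- score - s1 / s0
        info <- info + s2 / s0 - tcrossprod(s1 / s0)
      }
    }
  }
  list(ll = ll, score = score, info = info)
}

coxQuantities <- function(beta, time, status, X, strata, ties) {
  tot <- list(ll = 0, score = numeric(ncol(X)),
              info = matrix(0, ncol(X), ncol(X)))
  for (s in unique(strata)) {
    i <- strata == s
    q <- coxStratumQuantities(beta, time[i], status[i],
                              X[i, , drop = FALSE], ties)
    tot$ll <- tot$ll + q$ll
    tot$score <- tot$score + q$score
    tot$info <- tot$info + q$info
  }
  tot
}

#' Low-level Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood by damped Newton iteration from
#' `beta = 0`, with Efron (default) or Breslow handling of tied event
#' times and optional stratification (separate baseline hazard per
#' stratum). Convergence requires the largest score component to fall
#' below `tol`; a monotone likelihood (complete separation of events along
#' a covariate) is reported as a flagged non-convergent fit, never as
#' silent output.
#'
#' @param time numeric event/censoring times.
#' @param status 0/1 (1 = event).
#' @param X numeric covariate matrix (columns named).
#' @param strata optional stratum labels, one per row of `X`.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol score convergence tolerance.
#' @param maxIter maximum Newton iterations.
#' @return a [CoxFit].
#' @seealso [coxFit()] for the record-level interface.
#' @export
coxPH <- function(time, status, X, strata = NULL,
                  ties = c("efron", "breslow"), tol = 1e-8, maxIter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(strata)) strata <- rep(1L, length(time))
  status <- as.integer(status)
  if (sum(status) < 1L) stop("need at least one event to fit a Cox model")
  p <- ncol(X)
  beta <- numeric(p)
  q <- coxQuantities(beta, time, status, X, strata, ties)
  ll0 <- q$ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    if (max(abs(q$score)) < tol) { converged <- TRUE; break }
    step <- solve(q$info, q$score)
    newBeta <- beta + step
    newQ <- coxQuantities(newBeta, time, status, X, strata, ties)
    halvings <- 0L
    while (!is.finite(newQ$ll) || newQ$ll < q$ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      newBeta <- beta + step
      newQ <- coxQuantities(newBeta, time, status, X, strata, ties)
    }
    beta <- newBeta
    q <- newQ
    if (max(abs(beta)) > 15) break  # monotone likelihood guard
  }
  if (max(abs(q$score)) < tol && max(abs(beta)) <= 15) converged <- TRUE
  if (!converged)
    warning("Cox fit did not converge (possible monotone likelihood); ",
            "estimates not reliable")
  se <- if (converged) sqrt(diag(solve(q$info))) else rep(NA_real_, p)
  z <- beta / se
  names(beta) <- names(se) <- colnames(X)
  new("CoxFit",
      coefficients = beta,
      hazardRatios = exp(beta),
      se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
      nUsed = length(time), nEvents = sum(status),
      tiesMethod = ties,
      strata = if (length(unique(strata)) > 1L)
        sprintf("%d strata", length(unique(strata))) else "none",
      loglik = c(ll0, q$ll),
      converged = converged, iterations = iter)
}

#' Cox proportional-hazards fit on predation records
#'
#' Fits the log hazard of predation on treatment covariates for exposed
#' field records (typically after [firstAttackFilter()]). Covariates are
#' coded 0/1 with the cryptic colour (`green`) and the `solitary` group
#' treatment as reference levels; transect heterogeneity is handled by
#' stratification (separate baseline hazard per transect), the desk-scale
#' analogue of a transect random effect when there are only a couple of
#' transects.
#'
#' @param records survival record data.frame (exposed rows; mesh rows are
#'   dropped with a message).
#' @param covariates subset of `c("color", "group")`.
#' @param ties `"efron"` (default, daily ties) or `"breslow"`.
#' @param strata `"transect"` (default) or `"none"`.
#' @param subset `"all"` (default), `"group"` (group-of-10 treatments
#'   only) or `"solitary"`.
#' @return a [CoxFit]; its `nUsed` is the filtered record count.
#' @export
coxFit <- function(records, covariates = c("color", "group"),
                   ties = c("efron", "breslow"),
                   strata = c("transect", "none"),
                   subset = c("all", "group", "solitary")) {
  ties <- match.arg(ties)
  strata <- match.arg(strata)
  subset <- match.arg(subset)
  checkSurvivalRecords(records)
  covariates <- match.arg(covariates, c("color", "group"), several.ok = TRUE)
  if (any(records$exposed == "mesh")) {
    message("dropping ", sum(records$exposed == "mesh"),
            " mesh-bag record(s) from the Cox fit")
    records <- records[records$exposed != "mesh", , drop = FALSE]
  }
  if (subset == "group")
    records <- records[records$treatment_group == "group10", , drop = FALSE]
  if (subset == "solitary")
    records <- records[records$treatment_group == "solitary", , drop = FALSE]
  if (subset != "all") covariates <- setdiff(covariates, "group")
  if (!length(covariates)) stop("no covariates left to fit")
  X <- NULL
  if ("color" %in% covariates)
    X <- cbind(X, `color(yellow)` =
                 as.numeric(records$treatment_color == "yellow"))
  if ("group" %in% covariates)
    X <- cbind(X, `group(10)` =
                 as.numeric(records$treatment_group == "group10"))
  coxPH(time = records$event_day,
        status = as.integer(records$event == "died"),
        X = X,
        strata = if (strata == "transect") records$transect else NULL,
        ties = ties)
}

#' Mesh-bag control comparisons
#'
#' Two standard checks on the predator-exclusion control: (1) a binomial
#' mixed model of death (died/survived) on exposure (mesh bag vs exposed)
#' with a transect random intercept, establishing that mortality
#' differences among exposed treatments are due to predation; and (2) a
#' binomial GLM within the mesh bags of death on group-size and colour
#' treatment, establishing that neither affects background mortality.
#'
#' With a single transect in the data, the mixed model degrades to a plain
#' GLM with a note.
#'
#' @param records survival record data.frame containing both mesh and
#'   exposed rows.
#' @param nodes Gauss-Hermite nodes for the mixed model.
#' @return a list of two [ModelFit]s: `exposure` and `mesh_only`.
#' @export
meshComparison <- function(records, nodes = 15L) {
  checkSurvivalRecords(records)
  if (!any(records$exposed == "mesh") || !any(records$exposed == "exposed"))
    stop("need both mesh and exposed records")
  died <- as.integer(records$event == "died")
  Xexp <- cbind(`(Intercept)` = 1,
                `exposed` = as.numeric(records$exposed == "exposed"))
  exposure <- fitLogistic(died, Xexp, group = records$transect,
                          nodes = nodes,
                          formula = "died ~ exposed + (1 | transect)")
  mesh <- records[records$exposed == "mesh", , drop = FALSE]
  Xm <- cbind(`(Intercept)` = 1,
              `group(10)` = as.numeric(mesh$treatment_group == "group10"),
              `color(yellow)` = as.numeric(mesh$treatment_color == "yellow"))
  ## treatments absent from the mesh cells (constant columns) are dropped
  varies <- c(TRUE, apply(Xm[, -1L, drop = FALSE], 2L,
                          function(v) length(unique(v)) > 1L))
  Xm <- Xm[, varies, drop = FALSE]
  yMesh <- as.integer(mesh$event == "died")
  meshOnly <- if (length(unique(yMesh)) < 2L || ncol(Xm) < 2L) {
    ## no deaths (or no survivors) inside the bags: nothing to model
    new("ModelFit", estimates = numeric(), se = numeric(), z = numeric(),
        p = numeric(), ranefSD = NA_real_, family = "binomial",
        link = "logit", dispersion = 1, n = length(yMesh), nGroups = 0L,
        converged = FALSE, formula = "died ~ group + color (mesh only)",
        notes = paste("mesh-bag model not estimable (constant response",
                      "or no varying treatment)"))
  } else {
    fitLogistic(yMesh, Xm, group = NULL,
                formula = "died ~ group + color (mesh only)")
  }
  list(exposure = exposure, mesh_only = meshOnly)
}
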