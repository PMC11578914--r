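## Sequential measurement-invariance ladder with delta-fit decision rules and
## greedy refit-based partial-invariance search.

#' Configuration of the invariance ladder
#'
#' Decision rules per transition: a joint rule
#' \eqn{\Delta RMSEA \le 0.01} and \eqn{\Delta CFI \ge -0.004} for the
#' threshold and loading steps, and the stricter \eqn{\Delta CFI \ge -0.002}
#' for the intercept step. Partial invariance is accepted if at most
#' \code{budgetFraction} of the items must be released (default half,
#' i.e. 3 of 6).
#'
#' @param deltaRmseaMax maximum allowed RMSEA increase (threshold/loading
#'   steps).
#' @param deltaCfiMin minimum allowed CFI change (threshold/loading steps).
#' @param deltaCfiMinIntercepts minimum allowed CFI change (intercept step).
#' @param budgetFraction maximum fraction of items freed in partial search
#'   (capped at 1/2).
#' @return a list of class \code{LadderConfig}.
#' @export
ladderConfig <- function(deltaRmseaMax = 0.01, deltaCfiMin = -0.004,
                         deltaCfiMinIntercepts = -0.002,
                         budgetFraction = 0.5) {
  if (budgetFraction > 0.5) stop("partial-invariance budget cannot exceed half of the items")
  structure(list(deltaRmseaMax = deltaRmseaMax, deltaCfiMin = deltaCfiMin,
                 deltaCfiMinIntercepts = deltaCfiMinIntercepts,
                 budgetFraction = budgetFraction,
                 steps = c("configural", "thresholds", "loadings", "intercepts")),
            class = "LadderConfig")
}

#' Compare two nested invariance models by delta fit indices
#'
#' \eqn{\Delta CFI = CFI_{restricted} - CFI_{reference}} and
#' \eqn{\Delta RMSEA = RMSEA_{restricted} - RMSEA_{reference}}. The threshold
#' and loading transitions pass when both the \eqn{\Delta RMSEA} and
#' \eqn{\Delta CFI} bounds hold; the intercept transition uses the stricter
#' \eqn{\Delta CFI} bound alone. Chi-square difference tests are deliberately
#' not used.
#'
#' @param restricted the more constrained \linkS4class{CfaFit}.
#' @param reference the less constrained \linkS4class{CfaFit}.
#' @param step transition tag: \code{"thresholds"}, \code{"loadings"} or
#'   \code{"intercepts"}.
#' @param config a \code{\link{ladderConfig}}.
#' @return list with \code{pass}, \code{deltaCfi}, \code{deltaRmsea},
#'   \code{rule}.
#' @export
compareModels <- function(restricted, reference, step, config = ladderConfig()) {
  if (is(restricted, "CfaFit") && is(reference, "CfaFit")) {
    if (restricted@df <= reference@df)
      stop("models not nested: restricted model must have more degrees of freedom")
    dCfi <- unname(restricted@indices["cfi"] - reference@indices["cfi"])
    dRmsea <- unname(restricted@indices["rmsea"] - reference@indices["rmsea"])
  } else stop("supply two CfaFit objects")
  .applyRule(dCfi, dRmsea, step, config)
}

.applyRule <- function(dCfi, dRmsea, step, config) {
  step <- match.arg(step, c("thresholds", "loadings", "intercepts"))
  if (step == "intercepts") {
    pass <- dCfi >= config$deltaCfiMinIntercepts
    rule <- sprintf("deltaCFI >= %g", config$deltaCfiMinIntercepts)
  } else {
    pass <- (dRmsea <= config$deltaRmseaMax) && (dCfi >= config$deltaCfiMin)
    rule <- sprintf("deltaRMSEA <= %g & deltaCFI >= %g",
                    config$deltaRmseaMax, config$deltaCfiMin)
  }
  list(pass = pass, deltaCfi = dCfi, deltaRmsea = dRmsea, rule = rule, step = step)
}

## margin of a comparison under the step's rule (positive = passing, larger =
## more comfortably passing); used to rank candidate releases
.ruleMargin <- function(cmp, config) {
  if (cmp$step == "intercepts") cmp$deltaCfi - config$deltaCfiMinIntercepts
  else min(cmp$deltaCfi - config$deltaCfiMin,
           config$deltaRmseaMax - cmp$deltaRmsea)
}

#' Greedy partial-invariance search
#'
#' Frees, one item at a time, the item whose release most improves the failed
#' step's decision margin (each candidate is refit, not approximated), until
#' the step's rule passes or the budget is exceeded. Ties are broken by item
#' index.
#'
#' @param moments list of \linkS4class{PolychoricMoments} per group.
#' @param reference the less constrained \linkS4class{CfaFit} the step is
#'   compared against.
#' @param step the failed step ("thresholds", "loadings" or "intercepts").
#' @param config a \code{\link{ladderConfig}}.
#' @param freeItems item indices already freed at earlier steps (carried
#'   forward).
#' @param residualPairs correlated-residual pairs of the model.
#' @return list with \code{status} ("passed", "already-passing" or
#'   "noninvariant, partial invariance not achieved"), \code{freed} (ordered
#'   item indices released at this step), \code{fit} (final restricted fit,
#'   or NULL), and \code{comparison}.
#' @export
partialSearch <- function(moments, reference, step, config = ladderConfig(),
                          freeItems = list(), residualPairs = NULL) {
  K <- length(moments[[1]]@items)
  budget <- floor(config$budgetFraction * K)
  freedHere <- integer(0)
  fitWith <- function(extra) {
    fi <- freeItems
    fi[[step]] <- sort(unique(c(fi[[step]], extra)))
    m <- cfaModel(moments, level = step, residualPairs = residualPairs,
                  freeItems = fi)
    suppressWarnings(fitCfa(moments, m, warmFrom = reference,
                            checkIdentification = FALSE))
  }
  current <- fitWith(integer(0))
  cmp <- compareModels(current, reference, step, config)
  if (cmp$pass)
    return(list(status = "already-passing", freed = integer(0), fit = current,
                comparison = cmp))
  repeat {
    if (length(freedHere) >= budget)
      return(list(status = "noninvariant, partial invariance not achieved",
                  freed = freedHere, fit = current, comparison = cmp))
    candidates <- setdiff(seq_len(K), c(freedHere, freeItems[[step]]))
    if (!length(candidates))
      return(list(status = "noninvariant, partial invariance not achieved",
                  freed = freedHere, fit = current, comparison = cmp))
    fits <- lapply(candidates, function(j) fitWith(c(freedHere, j)))
    cmps <- lapply(fits, compareModels, reference = reference, step = step,
                   config = config)
    margins <- vapply(cmps, .ruleMargin, numeric(1), config = config)
    best <- which.max(margins)   # ties broken by item index (first max)
    freedHere <- c(freedHere, candidates[best])
    current <- fits[[best]]
    cmp <- cmps[[best]]
    if (cmp$pass)
      return(list(status = "passed", freed = freedHere, fit = current,
                  comparison = cmp))
  }
}

#' Run the sequential invariance ladder
#'
#' Fits the configural, equal-thresholds, equal-loadings and equal-intercepts
#' models across the groups of \code{grouping}, evaluates each transition
#' with \code{\link{compareModels}}, and invokes \code{\link{partialSearch}}
#' on failure. Latent means and variances are only comparable once at least
#' partial scalar invariance is achieved.
#'
#' @param dataset an \linkS4class{OrdinalDataset}, or a precomputed list of
#'   \linkS4class{PolychoricMoments}.
#' @param grouping grouping column(s) of the dataset.
#' @param residualPairs correlated-residual item pairs.
#' @param config a \code{\link{ladderConfig}}.
#' @param strict strict handling of empty categories.
#' @return a \linkS4class{LadderResult}.
#' @export
runLadder <- function(dataset, grouping = "label", residualPairs = NULL,
                      config = ladderConfig(), strict = FALSE) {
  moments <- if (is(dataset, "OrdinalDataset"))
    polyMomentsByGroup(dataset, grouping = grouping, strict = strict)
  else dataset
  if (length(moments) < 2L)
    stop("invariance testing requires at least 2 groups")
  stepNames <- config$steps
  fits <- list()
  freed <- list()
  rows <- list()
  levelNames <- c(configural = "configural", thresholds = "thresholds",
                  loadings = "metric", intercepts = "scalar")

  mConf <- cfaModel(moments, "configural", residualPairs = residualPairs)
  fits$configural <- suppressWarnings(fitCfa(moments, mConf))
  achieved <- "configural"
  rows[[1]] <- .ladderRow(fits$configural, "configural", NA, NA, NA, "")
  prevFit <- fits$configural
  partial <- FALSE

  for (step in stepNames[-1]) {
    m <- cfaModel(moments, step, residualPairs = residualPairs, freeItems = freed)
    fit <- suppressWarnings(fitCfa(moments, m, warmFrom = prevFit,
                                   checkIdentification = FALSE))
    cmp <- compareModels(fit, prevFit, step, config)
    if (cmp$pass) {
      fits[[step]] <- fit
      rows[[length(rows) + 1L]] <- .ladderRow(fit, step, cmp$deltaCfi,
                                              cmp$deltaRmsea, TRUE, "")
      prevFit <- fit
      achieved <- if (partial) paste0("partial-", unname(levelNames[step]))
        else unname(levelNames[step])
      next
    }
    ps <- partialSearch(moments, prevFit, step, config, freeItems = freed,
                        residualPairs = residualPairs)
    if (ps$status == "passed") {
      partial <- TRUE
      freed[[step]] <- sort(unique(c(freed[[step]], ps$freed)))
      fits[[step]] <- ps$fit
      rows[[length(rows) + 1L]] <- .ladderRow(ps$fit, paste0("partial-", step),
                                              ps$comparison$deltaCfi,
                                              ps$comparison$deltaRmsea, TRUE,
                                              paste(ps$freed, collapse = ","))
      prevFit <- ps$fit
      achieved <- paste0("partial-", levelNames[step])
    } else {
      rows[[length(rows) + 1L]] <- .ladderRow(fit, step, cmp$deltaCfi,
                                              cmp$deltaRmsea, FALSE, "")
      achieved <- paste0(achieved, " (", step, " noninvariant)")
      break
    }
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  new("LadderResult", steps = fits, comparisons = comparisons, freed = freed,
      level = achieved, grouping = paste(grouping, collapse = "+"),
      config = unclass(config))
}

.ladderRow <- function(fit, label, dCfi, dRmsea, pass, freedStr) {
  ix <- fit@indices
  data.frame(model = label, chisq = fit@chisq, df = fit@df,
             cfi = unname(ix["cfi"]), tli = unname(ix["tli"]),
             rmsea = unname(ix["rmsea"]), rmsea.lo = unname(ix["rmsea.lo"]),
             rmsea.hi = unname(ix["rmsea.hi"]), srmr = unname(ix["srmr"]),
             deltaCfi = dCfi, deltaRmsea = dRmsea, pass = pass,
             freed = freedStr, stringsAsFactors = FALSE)
}

#' Two-group convenience comparison
#'
#' Runs the invariance ladder restricted to two groups (e.g. an early versus
#' a late survey year), mirroring a two-group sensitivity design.
#'
#' @param dataset an \linkS4class{OrdinalDataset}.
#' @param groupA,groupB the two group labels to compare.
#' @param grouping grouping column.
#' @param ... passed to \code{\link{runLadder}}.
#' @return a \linkS4class{LadderResult}.
#' @export
runTwoGroup <- function(dataset, groupA, groupB, grouping = "label", ...) {
  f <- .groupFactor(dataset, grouping)
  keep <- f %in% c(groupA, groupB)
  sub <- new("OrdinalDataset", items = dataset@items[keep, , drop = FALSE],
             groups = data.frame(label = as.character(f[keep]),
                                 stringsAsFactors = FALSE),
             cluster = if (is.null(dataset@cluster)) NULL else dataset@cluster[keep],
             nCategories = dataset@nCategories, seed = dataset@seed)
  sub@groups$label <- factor(sub@groups$label, levels = c(groupA, groupB))
  sub@groups$label <- as.character(sub@groups$label)
  runLadder(sub, grouping = "label", ...)
}
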