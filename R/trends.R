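## Latent-mean trends under (partial) scalar invariance, freed-vs-fixed
## counterfactuals, the one-way ICC clustering check, and observed-score
## descriptives.

## variance of (kappa_g - kappa_ref)/sqrt(phi_ref) by the delta method
.devVar <- function(fit, gIdx, refIdx) {
  est <- fit@estimates
  rowOf <- function(type, g) which(est$type == type &
                                     est$group == fit@model@groups[g])
  parOf <- function(type, g) {
    r <- rowOf(type, g)
    if (est$free[r]) est$par[r] else 0L
  }
  pKg <- parOf("kappa", gIdx); pKr <- parOf("kappa", refIdx)
  pPr <- parOf("phi", refIdx)    # phi parameter is log-scale internally
  kg <- est$est[rowOf("kappa", gIdx)]
  kr <- est$est[rowOf("kappa", refIdx)]
  pr <- est$est[rowOf("phi", refIdx)]
  ## gradient wrt (kappa_g, kappa_ref, logphi_ref)
  grad <- c(1 / sqrt(pr), -1 / sqrt(pr), -(kg - kr) / (2 * sqrt(pr)))
  pars <- c(pKg, pKr, pPr)
  use <- pars > 0L
  if (!any(use)) return(0)
  V <- fit@vcov[pars[use], pars[use], drop = FALSE]
  as.numeric(t(grad[use]) %*% V %*% grad[use])
}

#' Latent-mean trend from a (partial) scalar model
#'
#' Standardized latent-mean deviations \eqn{(\hat\kappa_g -
#' \hat\kappa_{ref})/\sqrt{\hat\phi_{ref}}} with delta-method 95\% CIs,
#' centered on a chosen reference group. Requires at least partial scalar
#' invariance; re-centering on a different reference is an exact
#' transformation of the same fit (no refit).
#'
#' @param x a \linkS4class{LadderResult} that achieved (partial) scalar
#'   invariance, or the final \linkS4class{CfaFit} itself.
#' @param reference reference group label (default: first group).
#' @param level confidence level.
#' @return data.frame of class \code{TrendResult}: group, deviation, se,
#'   lower, upper, reference, variant.
#' @export
latentTrend <- function(x, reference = NULL, level = 0.95) {
  if (is(x, "LadderResult")) {
    if (!grepl("scalar", x@level))
      stop("latent means are not comparable: achieved level is '", x@level,
           "' (at least partial scalar invariance required)")
    fit <- x@steps$intercepts
    variant <- if (grepl("partial", x@level)) "partial scalar" else "full scalar"
  } else if (is(x, "CfaFit")) {
    if (x@model@level != "intercepts")
      stop("latent means require a scalar (equal-intercepts) model")
    fit <- x
    variant <- if (length(x@model@freeItems$intercepts)) "partial scalar" else "full scalar"
  } else stop("supply a LadderResult or CfaFit")
  groups <- fit@model@groups
  if (is.null(reference)) reference <- groups[1]
  refIdx <- match(reference, groups)
  if (is.na(refIdx)) stop("unknown reference group '", reference, "'")
  est <- fit@estimates
  kap <- vapply(seq_along(groups), function(g)
    est$est[est$type == "kappa" & est$group == groups[g]], numeric(1))
  phi <- vapply(seq_along(groups), function(g)
    est$est[est$type == "phi" & est$group == groups[g]], numeric(1))
  dev <- (kap - kap[refIdx]) / sqrt(phi[refIdx])
  se <- vapply(seq_along(groups), function(g) {
    if (g == refIdx) 0 else sqrt(max(.devVar(fit, g, refIdx), 0))
  }, numeric(1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(group = groups, deviation = dev, se = se,
                       lower = dev - z * se, upper = dev + z * se,
                       reference = reference, variant = variant,
                       stringsAsFactors = FALSE),
            class = c("TrendResult", "data.frame"))
}

#' Freed-versus-fixed counterfactual trends
#'
#' Fits two otherwise-identical scalar models — one freeing the designated
#' noninvariant parameters (partial scalar), one fixing them (full scalar) —
#' and compares the implied latent-mean trends. Quantifies how much ignoring
#' noninvariance would distort the trend.
#'
#' @param dataset an \linkS4class{OrdinalDataset} or list of
#'   \linkS4class{PolychoricMoments}.
#' @param noninvariantParams named list of item indices to free, e.g.
#'   \code{list(intercepts = 5L)} (from \code{\link{partialSearch}} or
#'   user-supplied).
#' @param grouping grouping column(s).
#' @param residualPairs correlated-residual pairs.
#' @param reference reference group for centering.
#' @param budgetFraction diagnostic warning threshold for the freed set size.
#' @return list with \code{freed} and \code{fixed} trend data.frames,
#'   \code{difference} per group, and \code{maxAbsDifference}.
#' @export
freedVsFixed <- function(dataset, noninvariantParams, grouping = "label",
                         residualPairs = NULL, reference = NULL,
                         budgetFraction = 0.5) {
  moments <- if (is(dataset, "OrdinalDataset"))
    polyMomentsByGroup(dataset, grouping = grouping)
  else dataset
  K <- length(moments[[1]]@items)
  nFreed <- length(unique(unlist(noninvariantParams)))
  if (nFreed > floor(budgetFraction * K))
    warning("freed set exceeds the partial-invariance budget (diagnostic mode)")
  mFix <- cfaModel(moments, "intercepts", residualPairs = residualPairs)
  fFix <- suppressWarnings(fitCfa(moments, mFix))
  mFree <- cfaModel(moments, "intercepts", residualPairs = residualPairs,
                    freeItems = noninvariantParams)
  fFree <- suppressWarnings(fitCfa(moments, mFree, warmFrom = fFix,
                                   checkIdentification = FALSE))
  tFix <- latentTrend(fFix, reference = reference)
  tFree <- latentTrend(fFree, reference = reference)
  tFix$variant <- "fixed-counterfactual"
  dif <- tFree$deviation - tFix$deviation
  list(freed = tFree, fixed = tFix,
       difference = data.frame(group = tFree$group, difference = dif,
                               stringsAsFactors = FALSE),
       maxAbsDifference = max(abs(dif)))
}

#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator of the ICC from an intercept-only clustering decomposition
#' (between-cluster vs within-cluster mean squares, with the unbalanced-design
#' average cluster size), truncated at 0.
#'
#' @param x numeric outcome (e.g. item scores); NAs dropped.
#' @param cluster cluster identifiers.
#' @return ICC estimate in [0, 1].
#' @export
iccOneway <- function(x, cluster) {
  ok <- !is.na(x) & !is.na(cluster)
  x <- x[ok]; cluster <- factor(cluster[ok])
  k <- nlevels(cluster)
  if (k < 2L) stop("at least 2 clusters required")
  ni <- tabulate(cluster)
  if (any(ni < 1L)) cluster <- droplevels(cluster)
  N <- length(x)
  gm <- mean(x)
  mi <- tapply(x, cluster, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((x - mi[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  if (msw == 0) return(if (msb > 0) 1 else 0)
  icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  max(icc, 0)
}

#' Observed-score descriptives per group
#'
#' Per-item mean, SD, skewness and excess kurtosis plus the 1..C scale mean
#' score (items averaged within respondent), per group.
#'
#' @param dataset an \linkS4class{OrdinalDataset}.
#' @param grouping grouping column(s).
#' @return data.frame: group, item (or "scale"), mean, sd, skewness,
#'   kurtosis (excess), n.
#' @export
describeItems <- function(dataset, grouping = "label") {
  f <- .groupFactor(dataset, grouping)
  K <- ncol(dataset@items)
  mom <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v); m <- mean(v); s <- stats::sd(v)
    z <- (v - m) / s
    c(mean = m, sd = s, skewness = mean(z^3),
      kurtosis = mean(z^4) - 3, n = n)
  }
  out <- list()
  for (g in levels(f)) {
    y <- dataset@items[f == g, , drop = FALSE]
    for (j in seq_len(K)) {
      r <- mom(y[, j])
      out[[length(out) + 1L]] <- data.frame(
        group = g, item = colnames(dataset@items)[j], t(r),
        stringsAsFactors = FALSE)
    }
    r <- mom(rowMeans(y, na.rm = TRUE))
    out[[length(out) + 1L]] <- data.frame(group = g, item = "scale", t(r),
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
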