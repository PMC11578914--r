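## Two-step polychoric moment estimation: univariate thresholds, pairwise
## maximum-likelihood correlations with thresholds fixed, and an
## influence-function estimate of the full asymptotic covariance of the
## moment vector (its diagonal is the DWLS weight source). Missing data are
## handled by pairwise deletion throughout.

#' Estimate thresholds of one ordinal item
#'
#' \eqn{\hat\tau_c = \Phi^{-1}} of the cumulative proportion through category
#' c. Empty categories (interior or marginal) are collapsed with the adjacent
#' category by default, with a warning; in strict mode they are an error.
#'
#' @param counts length-C vector of category counts (may be non-integer,
#'   e.g. expected counts).
#' @param strict error on empty categories instead of collapsing.
#' @return numeric vector of thresholds (length C-1 when no category is
#'   empty), with attributes \code{collapsed} (logical) and \code{mapping}
#'   (original category -> collapsed category).
#' @examples
#' estimateThresholds(c(25, 25, 25, 25))
#' @export
estimateThresholds <- function(counts, strict = FALSE) {
  if (any(counts < 0) || sum(counts) <= 0) stop("counts must be nonnegative with positive total")
  C <- length(counts)
  nz <- counts > 0
  if (sum(nz) < 2L) stop("item degenerate: all mass in one category")
  collapsed <- any(!nz)
  if (collapsed) {
    if (strict) stop("empty category present (strict mode): category ",
                     paste(which(!nz), collapse = ", "))
    warning("empty categor", if (sum(!nz) > 1L) "ies" else "y", " ",
            paste(which(!nz), collapse = ", "), " collapsed with adjacent")
  }
  mapping <- cumsum(nz)            # original category -> collapsed index
  mapping[mapping == 0L] <- 1L     # leading empties merge into first retained
  p <- counts[nz] / sum(counts)
  tau <- stats::qnorm(cumsum(p)[-length(p)])
  attr(tau, "collapsed") <- collapsed
  attr(tau, "mapping") <- mapping
  tau
}

## fast C1 x C2 cross-tabulation of complete pairs
.pairTable <- function(y1, y2, C1, C2) {
  ok <- !is.na(y1) & !is.na(y2)
  matrix(tabulate((y2[ok] - 1L) * C1 + y1[ok], nbins = C1 * C2), C1, C2)
}

## negative pairwise log-likelihood over rho, thresholds fixed
.polyNegLL <- function(rho, tab, tau1, tau2) {
  P <- .cellProbs(tau1, tau2, rho)
  -sum(tab * log(pmax(P, 1e-300)))
}

## score sum_cells n_ab * (dP/drho)/P
.polyScore <- function(rho, tab, tau1, tau2) {
  P <- pmax(.cellProbs(tau1, tau2, rho), 1e-300)
  dP <- .dcellProbs_drho(tau1, tau2, rho)
  sum(tab * dP / P)
}

#' Estimate a polychoric correlation from a contingency table
#'
#' Two-step estimator: maximizes the bivariate-normal multinomial likelihood
#' of the table over \eqn{\rho \in (-0.999, 0.999)} with the thresholds fixed
#' at their univariate estimates. A bracketed search is refined by Newton
#' steps to score tolerance 1e-8. A likelihood maximized at the boundary
#' yields a clipped estimate with a warning.
#'
#' @param tab C1 x C2 contingency table of pairwise-complete counts.
#' @param tau1,tau2 fixed threshold vectors of the two items.
#' @param tol tolerance of the bracketed search.
#' @param refine Newton-refine to score tolerance 1e-8 (skipped for bulk
#'   work such as parallel-analysis reference sets).
#' @return list with \code{rho}, \code{var} (asymptotic variance from the
#'   observed information of the one-parameter likelihood), and
#'   \code{boundary} flag.
#' @export
estimatePolychoric <- function(tab, tau1, tau2, tol = 1e-6, refine = TRUE) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  n <- sum(tab)
  bound <- 0.999
  opt <- stats::optimize(.polyNegLL, c(-bound, bound), tab = tab,
                         tau1 = tau1, tau2 = tau2, tol = tol)
  rho <- opt$minimum
  boundary <- FALSE
  ## Newton refinement on the score
  if (refine) for (it in 1:12) {
    sc <- .polyScore(rho, tab, tau1, tau2)
    if (abs(sc) < 1e-8 * max(1, n)) break
    h <- 1e-5
    dsc <- (.polyScore(rho + h, tab, tau1, tau2) -
              .polyScore(rho - h, tab, tau1, tau2)) / (2 * h)
    if (!is.finite(dsc) || dsc >= 0) break
    step <- sc / dsc
    rho <- rho - sign(step) * min(abs(step), 0.1)
    if (abs(rho) >= bound) { rho <- sign(rho) * bound; boundary <- TRUE; break }
  }
  if (abs(rho) >= bound - 1e-6) {
    boundary <- TRUE
    rho <- sign(rho) * bound
    warning("polychoric likelihood maximized at the boundary; estimate clipped")
  }
  if (!refine)
    return(list(rho = rho, var = NA_real_, boundary = boundary))
  ## observed information of the profile likelihood (numerical, central)
  h <- 1e-4
  info <- -(.polyScore(min(rho + h, bound), tab, tau1, tau2) -
              .polyScore(max(rho - h, -bound), tab, tau1, tau2)) /
    (min(rho + h, bound) - max(rho - h, -bound))
  v <- if (is.finite(info) && info > 0) 1 / info else NA_real_
  list(rho = rho, var = v, boundary = boundary)
}

## numerical derivative of the mean score wrt one threshold component
.meanScore <- function(rho, phat, tau1, tau2) {
  P <- pmax(.cellProbs(tau1, tau2, rho), 1e-300)
  dP <- .dcellProbs_drho(tau1, tau2, rho)
  sum(phat * dP / P)
}

#' Polychoric moments and asymptotic weights for one group
#'
#' Assembles the full sample-moment vector of a group: thresholds for every
#' item, all pairwise polychoric correlations, pairwise-complete sample
#' sizes, and an influence-function estimate of the asymptotic covariance of
#' the moment vector (accounting for two-step threshold estimation and for
#' pairwise deletion). The diagonal of that covariance supplies the DWLS
#' weights; the full matrix feeds the robust test-statistic correction and
#' sandwich standard errors.
#'
#' @param dataset an \linkS4class{OrdinalDataset} or integer matrix.
#' @param group group label to slice (ignored for a matrix).
#' @param grouping grouping column(s) of the dataset.
#' @param strict error on empty categories instead of collapsing.
#' @return a \linkS4class{PolychoricMoments}.
#' @export
polyMoments <- function(dataset, group = NULL, grouping = "label", strict = FALSE) {
  if (is(dataset, "OrdinalDataset")) {
    f <- .groupFactor(dataset, grouping)
    if (is.null(group)) {
      if (nlevels(f) > 1L) stop("dataset has several groups; supply 'group'")
      group <- levels(f)[1]
    }
    y <- dataset@items[f == group, , drop = FALSE]
    C <- dataset@nCategories
  } else {
    y <- as.matrix(dataset)
    if (is.null(group)) group <- "all"
    C <- max(y, na.rm = TRUE)
  }
  K <- ncol(y)
  if (K < 2L) stop("at least 2 items required")
  n <- nrow(y)
  items <- colnames(y)
  if (is.null(items)) items <- paste0("item_", seq_len(K))

  tauList <- vector("list", K)
  nItem <- integer(K)
  for (j in seq_len(K)) {
    cnt <- tabulate(y[, j], nbins = C)
    tau <- tryCatch(estimateThresholds(cnt, strict = strict),
                    error = function(e) stop(sprintf("item %d ('%s'): %s",
                                                     j, items[j], conditionMessage(e)),
                                             call. = FALSE))
    if (isTRUE(attr(tau, "collapsed")))   # recode the column to the collapsed scale
      y[, j] <- attr(tau, "mapping")[y[, j]]
    tauList[[j]] <- as.numeric(tau)
    nItem[j] <- sum(!is.na(y[, j]))
  }
  Cj <- lengths(tauList) + 1L

  nThr <- sum(Cj - 1L)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  npairs <- nrow(pairs)
  M <- nThr + npairs
  thrOffset <- c(0L, cumsum(Cj - 1L))

  IF <- matrix(0, n, M)
  ## threshold influence functions
  for (j in seq_len(K)) {
    obs <- !is.na(y[, j])
    scale <- n / nItem[j]
    tau <- tauList[[j]]
    for (cc in seq_along(tau)) {
      Pc <- stats::pnorm(tau[cc])
      col <- thrOffset[j] + cc
      IF[obs, col] <- ((y[obs, j] <= cc) - Pc) / stats::dnorm(tau[cc]) * scale
    }
  }

  P <- diag(1, K)
  pairN <- matrix(n, K, K)
  rhoIdx <- function(i) nThr + i
  for (i in seq_len(npairs)) {
    j <- pairs[i, 1]; k <- pairs[i, 2]
    tab <- .pairTable(y[, j], y[, k], Cj[j], Cj[k])
    njk <- sum(tab)
    pairN[j, k] <- pairN[k, j] <- njk
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop(sprintf("pair (%d, %d): contingency table has a zero margin", j, k))
    est <- suppressWarnings(estimatePolychoric(tab, tauList[[j]], tauList[[k]]))
    rho <- est$rho
    P[j, k] <- P[k, j] <- rho

    ## per-cell scores and two-step correction
    phat <- tab / njk
    Pi <- pmax(.cellProbs(tauList[[j]], tauList[[k]], rho), 1e-300)
    dPi <- .dcellProbs_drho(tauList[[j]], tauList[[k]], rho)
    s_cell <- dPi / Pi
    h <- 1e-4
    Hrr <- -(.meanScore(rho + h, phat, tauList[[j]], tauList[[k]]) -
               .meanScore(rho - h, phat, tauList[[j]], tauList[[k]])) / (2 * h)
    if (!is.finite(Hrr) || Hrr <= 0) Hrr <- sum(phat * s_cell^2)
    ## d meanscore / d tau components (numerical, central differences)
    Hrt1 <- vapply(seq_along(tauList[[j]]), function(cc) {
      tp <- tm <- tauList[[j]]; tp[cc] <- tp[cc] + h; tm[cc] <- tm[cc] - h
      (.meanScore(rho, phat, tp, tauList[[k]]) -
         .meanScore(rho, phat, tm, tauList[[k]])) / (2 * h)
    }, numeric(1))
    Hrt2 <- vapply(seq_along(tauList[[k]]), function(cc) {
      tp <- tm <- tauList[[k]]; tp[cc] <- tp[cc] + h; tm[cc] <- tm[cc] - h
      (.meanScore(rho, phat, tauList[[j]], tp) -
         .meanScore(rho, phat, tauList[[j]], tm)) / (2 * h)
    }, numeric(1))

    ok <- !is.na(y[, j]) & !is.na(y[, k])
    sObs <- numeric(n)
    sObs[ok] <- s_cell[cbind(y[ok, j], y[ok, k])] * (n / njk)
    corr <- IF[, thrOffset[j] + seq_along(Hrt1), drop = FALSE] %*% Hrt1 +
      IF[, thrOffset[k] + seq_along(Hrt2), drop = FALSE] %*% Hrt2
    IF[, rhoIdx(i)] <- (sObs + as.numeric(corr)) / Hrr
  }

  Gam <- crossprod(IF) / n
  new("PolychoricMoments", group = as.character(group), items = items,
      thresholds = tauList, rho = P, acov = Gam, pairN = pairN,
      n = as.integer(n))
}

#' Polychoric moments for every group of a dataset
#'
#' @param dataset an \linkS4class{OrdinalDataset}.
#' @param grouping grouping column(s).
#' @param strict error on empty categories instead of collapsing.
#' @return named list of \linkS4class{PolychoricMoments}, in group order.
#' @export
polyMomentsByGroup <- function(dataset, grouping = "label", strict = FALSE) {
  f <- .groupFactor(dataset, grouping)
  out <- lapply(levels(f), function(g) {
    sub <- new("OrdinalDataset",
               items = dataset@items[f == g, , drop = FALSE],
               groups = data.frame(label = rep(g, sum(f == g)), stringsAsFactors = FALSE),
               cluster = NULL, nCategories = dataset@nCategories,
               seed = dataset@seed)
    polyMoments(sub, group = g, strict = strict)
  })
  names(out) <- levels(f)
  out
}
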