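## Factor-retention by parallel analysis and the eigenvalue-ratio rule.

## correlation matrix of an ordinal data matrix (polychoric or Pearson,
## pairwise complete); thresholds may be precomputed (margins fixed)
.ordCorMatrix <- function(y, C, method, tauList = NULL) {
  K <- ncol(y)
  if (method == "pearson")
    return(stats::cor(y, use = "pairwise.complete.obs"))
  if (is.null(tauList))
    tauList <- lapply(seq_len(K), function(j) {
      tau <- estimateThresholds(tabulate(y[, j], nbins = C))
      if (isTRUE(attr(tau, "collapsed"))) y[, j] <<- attr(tau, "mapping")[y[, j]]
      as.numeric(tau)
    })
  Cj <- lengths(tauList) + 1L
  P <- diag(1, K)
  for (j in seq_len(K - 1L)) for (k in (j + 1L):K) {
    tab <- .pairTable(y[, j], y[, k], Cj[j], Cj[k])
    est <- suppressWarnings(estimatePolychoric(tab, tauList[[j]], tauList[[k]],
                                               tol = 1e-4, refine = FALSE))
    P[j, k] <- P[k, j] <- est$rho
  }
  P
}

#' Parallel analysis with the eigenvalue-ratio rule
#'
#' Compares the observed eigenvalues of the item correlation matrix with a
#' percentile of eigenvalues from reference datasets of identical dimensions.
#' Reference data are column-wise permutations of the observed responses
#' (preserving the marginal category distributions); an independent
#' multinomial scheme is available. Retention counts components sequentially
#' from the first whose observed eigenvalue exceeds its reference percentile.
#' The first-to-second eigenvalue ratio > 4 flags essential
#' unidimensionality.
#'
#' @param x an \linkS4class{OrdinalDataset}, or an integer response matrix.
#' @param group optional group label to slice (with \code{grouping}).
#' @param grouping grouping column(s) of a dataset.
#' @param nSets number of reference datasets (default 200).
#' @param percentile reference eigenvalue percentile (default 95).
#' @param corMethod \code{"polychoric"} (default, consistent with the ordinal
#'   CFA) or \code{"pearson"}.
#' @param referenceScheme \code{"permutation"} (default, preserves margins)
#'   or \code{"multinomial"}.
#' @param seed integer seed.
#' @param minRows minimum rows required (default 50).
#' @return a \linkS4class{DimensionalityReport}.
#' @export
parallelAnalysis <- function(x, group = NULL, grouping = "label", nSets = 200L,
                             percentile = 95, corMethod = c("polychoric", "pearson"),
                             referenceScheme = c("permutation", "multinomial"),
                             seed = 1L, minRows = 50L) {
  corMethod <- match.arg(corMethod)
  referenceScheme <- match.arg(referenceScheme)
  if (is(x, "OrdinalDataset")) {
    if (!is.null(group)) {
      f <- .groupFactor(x, grouping)
      y <- x@items[f == group, , drop = FALSE]
    } else y <- x@items
    C <- x@nCategories
  } else {
    y <- as.matrix(x)
    C <- max(y, na.rm = TRUE)
  }
  n <- nrow(y); K <- ncol(y)
  if (n < minRows) stop(sprintf("group has %d rows; at least %d required", n, minRows))

  ## recode collapsed categories once; thresholds are reused for all
  ## permutation reference sets (margins are preserved)
  tauList <- vector("list", K)
  for (j in seq_len(K)) {
    tau <- estimateThresholds(tabulate(y[, j], nbins = C))
    if (isTRUE(attr(tau, "collapsed"))) y[, j] <- attr(tau, "mapping")[y[, j]]
    tauList[[j]] <- as.numeric(tau)
    if (length(tauList[[j]]) < 1L) stop(sprintf("item %d degenerate", j))
  }
  obsCor <- tryCatch(.ordCorMatrix(y, C, corMethod, tauList),
                     error = function(e) {
                       warning("polychoric estimation failed; falling back to Pearson")
                       .ordCorMatrix(y, C, "pearson")
                     })
  ev <- sort(eigen(obsCor, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)

  set.seed(.childSeed(seed, 104729L))
  refEv <- matrix(0, nSets, K)
  probs <- lapply(seq_len(K), function(j) {
    tb <- tabulate(y[, j], nbins = max(y[, j], na.rm = TRUE))
    tb / sum(tb)
  })
  for (b in seq_len(nSets)) {
    yb <- if (referenceScheme == "permutation") {
      apply(y, 2L, sample, size = n)
    } else {
      vapply(seq_len(K), function(j)
        sample.int(length(probs[[j]]), n, replace = TRUE, prob = probs[[j]]),
        integer(n))
    }
    Rb <- tryCatch(.ordCorMatrix(yb, C, corMethod,
                                 if (referenceScheme == "permutation") tauList else NULL),
                   error = function(e) .ordCorMatrix(yb, C, "pearson"))
    refEv[b, ] <- sort(eigen(Rb, symmetric = TRUE, only.values = TRUE)$values,
                       decreasing = TRUE)
  }
  refQ <- apply(refEv, 2L, stats::quantile, probs = percentile / 100, names = FALSE)
  exceeds <- ev > refQ
  retained <- if (exceeds[1]) {
    r <- which(!exceeds)
    if (length(r)) r[1] - 1L else K
  } else 0L
  ratio <- ev[1] / ev[2]
  new("DimensionalityReport", eigenvalues = ev, reference = refQ,
      retained = as.integer(retained), ratio = ratio,
      unidimensional = ratio > 4, nSets = as.integer(nSets),
      percentile = percentile, corMethod = corMethod, seed = as.integer(seed))
}

#' Scree-style table of a dimensionality report
#'
#' @param report a \linkS4class{DimensionalityReport}.
#' @return data.frame: component, observed eigenvalue, reference percentile
#'   eigenvalue — ready for plotting.
#' @export
screeTable <- function(report) {
  data.frame(component = seq_along(report@eigenvalues),
             observed = report@eigenvalues,
             reference = report@reference)
}
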