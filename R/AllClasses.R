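#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PopulationSpec: generating parameters of a multi-group ordinal factor model
#'
#' Per-group parameters of a one-factor normal-ogive (graded) model: latent
#' mean \code{kappa} and variance \code{phi}, loadings \code{lambda}, latent
#' response intercepts \code{nu}, thresholds \code{tau} (strictly increasing
#' per item), residual variances \code{theta}, and residual correlation pairs
#' \code{rho}. The first group is the reference: \code{kappa = 0},
#' \code{phi = 1}, and by default residual variances standardize the latent
#' response (\code{theta = 1 - lambda^2 * phi}, delta-style).
#'
#' @slot items character, item names.
#' @slot nCategories integer, number of response categories C.
#' @slot groupInfo data.frame with one row per group: \code{label},
#'   \code{n}, optional grid columns (e.g. year, gender, age), optional
#'   \code{nClusters}, \code{clusterSd}.
#' @slot params named list (one per group) with elements \code{kappa},
#'   \code{phi}, \code{lambda}, \code{nu}, \code{tau} (K x (C-1) matrix),
#'   \code{theta}, \code{rho} (npairs vector, possibly length 0).
#' @slot residualPairs integer matrix (npairs x 2) of item index pairs with
#'   correlated residuals.
#' @slot missRate item-level missingness probability in [0, 1).
#' @slot missMode \code{"MCAR"} (default) or \code{"MAR"} (probability
#'   increasing in the latent trait).
#' @slot marSlope logistic slope of the MAR mechanism (ignored for MCAR).
#' @slot injections data.frame log of noninvariance injections.
#' @export
setClass("PopulationSpec", representation(
  items = "character", nCategories = "integer", groupInfo = "data.frame",
  params = "list", residualPairs = "matrix", missRate = "numeric",
  missMode = "character", marSlope = "numeric", injections = "data.frame"))

setValidity("PopulationSpec", function(object) {
  K <- length(object@items); C <- object@nCategories
  if (C < 2L) return("nCategories must be >= 2")
  if (nrow(object@groupInfo) < 1L) return("at least one group required")
  if (!all(c("label", "n") %in% names(object@groupInfo)))
    return("groupInfo must have 'label' and 'n' columns")
  if (any(object@groupInfo$n < 1)) return("group sizes must be positive")
  if (object@missRate < 0 || object@missRate >= 1)
    return("missRate must be in [0, 1)")
  npairs <- nrow(object@residualPairs)
  for (g in seq_along(object@params)) {
    p <- object@params[[g]]
    lab <- object@groupInfo$label[g]
    if (length(p$lambda) != K || length(p$nu) != K || length(p$theta) != K)
      return(sprintf("group '%s': lambda/nu/theta must have length %d", lab, K))
    if (!all(dim(p$tau) == c(K, C - 1L)))
      return(sprintf("group '%s': tau must be %d x %d", lab, K, C - 1L))
    if (p$phi <= 0) return(sprintf("group '%s': phi must be > 0", lab))
    if (any(p$theta <= 0))
      return(sprintf("group '%s': theta must be > 0 (item %d)",
                     lab, which(p$theta <= 0)[1]))
    if (C > 2L) {
      bad <- which(apply(p$tau, 1L, function(z) any(diff(z) <= 0)))
      if (length(bad))
        return(sprintf("group '%s': thresholds not strictly increasing for item %d",
                       lab, bad[1]))
    }
    if (length(p$rho) != npairs)
      return(sprintf("group '%s': rho must have length %d", lab, npairs))
    if (npairs && any(abs(p$rho) >= 1))
      return(sprintf("group '%s': |rho| must be < 1", lab))
  }
  p1 <- object@params[[1]]
  if (abs(p1$kappa) > 1e-12 || abs(p1$phi - 1) > 1e-12)
    return("reference (first) group must have kappa = 0, phi = 1")
  TRUE
})

#' OrdinalDataset: item responses with group labels
#'
#' @slot items integer matrix (n x K) of responses in 1..C, NA = missing.
#' @slot groups data.frame with a \code{label} column (analysis group) and
#'   optional grid columns.
#' @slot cluster optional character vector of cluster IDs.
#' @slot nCategories integer C.
#' @slot seed integer seed the dataset was generated with (NA if read from file).
#' @export
setClass("OrdinalDataset", representation(
  items = "matrix", groups = "data.frame", cluster = "characterOrNULL",
  nCategories = "integer", seed = "integer"))

setValidity("OrdinalDataset", function(object) {
  v <- object@items[!is.na(object@items)]
  if (length(v) && (any(v < 1) || any(v > object@nCategories) || any(v != round(v))))
    return("responses must be integers in 1..nCategories or NA")
  if (nrow(object@groups) != nrow(object@items))
    return("groups must have one row per observation")
  if (!is.null(object@cluster) && length(object@cluster) != nrow(object@items))
    return("cluster must have one entry per observation")
  TRUE
})

#' PolychoricMoments: sample moments of one group
#'
#' Thresholds, polychoric correlations, influence-function asymptotic
#' covariance (whose diagonal is the DWLS weight source), and pairwise
#' sample sizes, estimated with pairwise deletion.
#'
#' @slot group group label.
#' @slot items item names.
#' @slot thresholds list of per-item threshold vectors.
#' @slot rho K x K polychoric correlation matrix.
#' @slot acov full asymptotic covariance of the moment vector
#'   (thresholds stacked by item, then correlations j < k column-wise),
#'   scaled for sqrt(n) convergence.
#' @slot pairN K x K matrix of pairwise-complete sample sizes.
#' @slot n number of rows in the group.
#' @export
setClass("PolychoricMoments", representation(
  group = "character", items = "character", thresholds = "list",
  rho = "matrix", acov = "matrix", pairN = "matrix", n = "integer"))

setValidity("PolychoricMoments", function(object) {
  P <- object@rho
  if (!isTRUE(all.equal(P, t(P), tolerance = 1e-8))) return("rho must be symmetric")
  if (any(abs(diag(P) - 1) > 1e-10)) return("rho must have unit diagonal")
  off <- P[upper.tri(P)]
  if (any(abs(off) >= 1)) return("off-diagonal correlations must be in (-1, 1)")
  for (j in seq_along(object@thresholds)) {
    tj <- object@thresholds[[j]]
    if (length(tj) > 1L && any(diff(tj) <= 0))
      return(sprintf("thresholds of item %d not strictly increasing", j))
  }
  if (any(diag(object@acov) <= 0)) return("asymptotic variances must be > 0")
  TRUE
})

#' CfaModel: a one-factor ordinal CFA model with group constraints
#'
#' The parameter template encodes, for every group-level parameter, whether it
#' is free, fixed, or tied to an equality set across groups, realizing one
#' identification schedule per invariance level under the delta
#' parameterization.
#'
#' @slot items item names.
#' @slot nCategories integer C.
#' @slot groups group labels.
#' @slot residualPairs integer matrix (npairs x 2).
#' @slot level invariance level tag: configural, thresholds, loadings,
#'   intercepts.
#' @slot freeItems named list of item indices freed per step (partial
#'   invariance).
#' @slot template data.frame parameter map (type, item, cat, pair, group,
#'   free, value, par).
#' @export
setClass("CfaModel", representation(
  items = "character", nCategories = "integer", groups = "character",
  residualPairs = "matrix", level = "character", freeItems = "list",
  template = "data.frame"))

#' CfaFit: a fitted ordinal CFA
#'
#' @slot model the CfaModel.
#' @slot estimates template data.frame with estimated values and standard
#'   errors.
#' @slot theta free-parameter vector at the optimum.
#' @slot vcov sandwich covariance of the free parameters.
#' @slot F minimized fit-function value (sum over groups of n_g * F_g).
#' @slot chisq mean-and-variance adjusted (scaled-and-shifted) test statistic.
#' @slot chisqMean mean-adjusted-only statistic (fallback, flagged).
#' @slot df model degrees of freedom.
#' @slot indices named numeric: cfi, tli, rmsea, rmsea.lo, rmsea.hi, srmr.
#' @slot baseline named numeric: chisq and df of the null model.
#' @slot nObs per-group sample sizes.
#' @slot converged logical.
#' @slot diagnostics list (iterations, gradient norm, Heywood flags, scale
#'   factors).
#' @export
setClass("CfaFit", representation(
  model = "CfaModel", estimates = "data.frame", theta = "numeric",
  vcov = "matrix", F = "numeric", chisq = "numeric", chisqMean = "numeric",
  df = "numeric", indices = "numeric", baseline = "numeric",
  nObs = "numeric", converged = "logical", diagnostics = "list"))

setValidity("CfaFit", function(object) {
  if (object@F < -1e-8) return("fit function must be >= 0")
  if (object@df < 0) return("df must be >= 0")
  TRUE
})

#' LadderResult: the sequential invariance ladder
#'
#' @slot steps named list of CfaFit objects (configural, thresholds, loadings,
#'   intercepts), possibly partial.
#' @slot comparisons data.frame of per-transition delta indices and decisions.
#' @slot freed named list of freed item indices per step.
#' @slot level achieved invariance level: configural, thresholds, metric,
#'   scalar, partial-scalar, or noninvariant variants.
#' @slot grouping name of the grouping column used.
#' @slot config the LadderConfig list used (rules, budget).
#' @export
setClass("LadderResult", representation(
  steps = "list", comparisons = "data.frame", freed = "list",
  level = "character", grouping = "character", config = "list"))

#' DimensionalityReport: parallel analysis and eigenvalue-ratio rule
#'
#' @slot eigenvalues observed eigenvalues of the item correlation matrix.
#' @slot reference per-component reference percentile eigenvalues.
#' @slot retained number of components retained.
#' @slot ratio first-to-second eigenvalue ratio.
#' @slot unidimensional logical flag (ratio > 4).
#' @slot nSets number of parallel datasets.
#' @slot percentile reference percentile used.
#' @slot corMethod correlation type ("polychoric" or "pearson").
#' @slot seed seed used.
#' @export
setClass("DimensionalityReport", representation(
  eigenvalues = "numeric", reference = "numeric", retained = "integer",
  ratio = "numeric", unidimensional = "logical", nSets = "integer",
  percentile = "numeric", corMethod = "character", seed = "integer"))

setValidity("DimensionalityReport", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strict = FALSE))
    return("eigenvalues must be non-increasing")
  TRUE
})
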