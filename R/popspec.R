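## Construction and modification of generating specifications (the DGP).

.expandPerGroup <- function(x, K, G, what) {
  ## accepts scalar, length-K vector, or K x G matrix; returns K x G matrix
  if (is.matrix(x)) {
    if (!all(dim(x) == c(K, G))) stop(sprintf("'%s' matrix must be %d x %d", what, K, G))
    return(x)
  }
  if (length(x) == 1L) x <- rep(x, K)
  if (length(x) != K) stop(sprintf("'%s' must be scalar, length %d, or %d x %d", what, K, K, G))
  matrix(x, K, G)
}

.expandScalarPerGroup <- function(x, G, what) {
  if (length(x) == 1L) x <- rep(x, G)
  if (length(x) != G) stop(sprintf("'%s' must be scalar or length %d", what, G))
  x
}

#' Build a population specification for the ordinal factor model generator
#'
#' Creates a fully populated, validated \linkS4class{PopulationSpec}. Omitted
#' parameters fall back to defaults emulating a six-item, four-category
#' symptom inventory: \code{lambda = 0.75}, \code{kappa = 0}, \code{phi = 1},
#' \code{nu = 0}, right-skewed default thresholds, and residual variances
#' standardizing the latent response in every group
#' (\code{theta = 1 - lambda^2 * phi}, delta-style), so the first group has
#' \code{Var(y*) = 1} exactly.
#'
#' @param groups character vector of group labels, or a data.frame with a
#'   \code{label} column plus optional grid columns (see
#'   \code{\link{makeGroupGrid}}).
#' @param n per-group sample sizes (scalar or vector).
#' @param nItems number of items K.
#' @param nCategories number of categories C.
#' @param lambda loadings: scalar, length-K, or K x G matrix.
#' @param kappa latent means per group (first group must be 0).
#' @param phi latent variances per group (first group must be 1).
#' @param nu latent-response intercepts: scalar, length-K, or K x G.
#' @param tau thresholds: length C-1 vector (common), K x (C-1) matrix
#'   (common across groups), or list of such matrices per group. Default:
#'   \code{qnorm(cumsum(c(0.55, 0.25, 0.12)))}, a right-skewed distribution
#'   typical of community symptom items.
#' @param theta residual variances (scalar/length-K/K x G); default
#'   \code{1 - lambda^2 * phi} per group.
#' @param residualPairs integer matrix (npairs x 2) of correlated-residual
#'   item pairs, or NULL.
#' @param rho residual correlations, one per pair (recycled across groups) or
#'   npairs x G matrix.
#' @param missRate item-level missingness probability in [0, 1).
#' @param missMode \code{"MCAR"} (default) or \code{"MAR"}.
#' @param marSlope slope of the MAR logistic mechanism in the latent trait.
#' @param nClusters,clusterSd optional cluster structure per group: number of
#'   clusters and the SD of a cluster-level shift added to the latent trait.
#' @return a \linkS4class{PopulationSpec}.
#' @examples
#' spec <- popSpec(groups = paste0("g", 1:4), n = 500)
#' spec
#' @export
popSpec <- function(groups = c("g1", "g2"), n = 1000, nItems = 6L,
                    nCategories = 4L, lambda = 0.75, kappa = 0, phi = 1,
                    nu = 0, tau = NULL, theta = NULL,
                    residualPairs = NULL, rho = 0.2,
                    missRate = 0, missMode = c("MCAR", "MAR"),
                    marSlope = 0.5, nClusters = 0L, clusterSd = 0) {
  missMode <- match.arg(missMode)
  K <- as.integer(nItems); C <- as.integer(nCategories)
  if (is.data.frame(groups)) {
    groupInfo <- groups
    if (!"label" %in% names(groupInfo)) stop("groups data.frame needs a 'label' column")
  } else {
    groupInfo <- data.frame(label = as.character(groups), stringsAsFactors = FALSE)
  }
  G <- nrow(groupInfo)
  groupInfo$n <- .expandScalarPerGroup(n, G, "n")
  groupInfo$nClusters <- .expandScalarPerGroup(as.integer(nClusters), G, "nClusters")
  groupInfo$clusterSd <- .expandScalarPerGroup(clusterSd, G, "clusterSd")

  lam <- .expandPerGroup(lambda, K, G, "lambda")
  nuM <- .expandPerGroup(nu, K, G, "nu")
  kap <- .expandScalarPerGroup(kappa, G, "kappa")
  ph <- .expandScalarPerGroup(phi, G, "phi")

  if (is.null(tau)) tau <- stats::qnorm(cumsum(c(0.55, 0.25, 0.12))[seq_len(C - 1L)])
  tauList <- vector("list", G)
  for (g in seq_len(G)) {
    tg <- if (is.list(tau)) tau[[g]] else tau
    if (!is.matrix(tg)) tg <- matrix(tg, K, C - 1L, byrow = TRUE)
    if (!all(dim(tg) == c(K, C - 1L)))
      stop(sprintf("tau must give %d x %d thresholds (group %d)", K, C - 1L, g))
    tauList[[g]] <- tg
  }

  if (is.null(residualPairs)) {
    residualPairs <- matrix(integer(0), 0L, 2L)
  } else {
    residualPairs <- matrix(as.integer(residualPairs), ncol = 2L)
    if (any(residualPairs < 1L | residualPairs > K))
      stop("residualPairs reference nonexistent items")
  }
  npairs <- nrow(residualPairs)
  rhoM <- if (npairs) {
    if (is.matrix(rho)) rho else matrix(rep_len(rho, npairs), npairs, G)
  } else matrix(numeric(0), 0L, G)

  thetaM <- if (is.null(theta)) {
    sweep(-(lam^2), 2L, ph, `*`) + 1   # 1 - lambda^2 * phi per group
  } else .expandPerGroup(theta, K, G, "theta")
  if (any(thetaM <= 0))
    stop("implied/supplied residual variance <= 0; reduce 'lambda' or supply 'theta'")

  params <- lapply(seq_len(G), function(g) list(
    kappa = kap[g], phi = ph[g], lambda = lam[, g], nu = nuM[, g],
    tau = tauList[[g]], theta = thetaM[, g],
    rho = if (npairs) rhoM[, g] else numeric(0)))
  names(params) <- groupInfo$label

  obj <- new("PopulationSpec", items = paste0("item_", seq_len(K)),
             nCategories = C, groupInfo = groupInfo, params = params,
             residualPairs = residualPairs, missRate = missRate,
             missMode = missMode, marSlope = marSlope,
             injections = data.frame(item = integer(0), parameter = character(0),
                                     shift = numeric(0), group = character(0),
                                     stringsAsFactors = FALSE))
  validObject(obj)
  ## residual covariance must be positive definite in every group
  for (g in seq_len(G)) {
    Th <- .residCov(obj, g)
    if (min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(sprintf("residual covariance not positive definite in group '%s'",
                   groupInfo$label[g]))
  }
  obj
}

## residual covariance matrix of group g
.residCov <- function(spec, g) {
  p <- spec@params[[g]]
  K <- length(p$theta)
  Th <- diag(p$theta, K)
  rp <- spec@residualPairs
  if (nrow(rp)) for (i in seq_len(nrow(rp))) {
    j <- rp[i, 1]; k <- rp[i, 2]
    Th[j, k] <- Th[k, j] <- p$rho[i] * sqrt(p$theta[j] * p$theta[k])
  }
  Th
}

#' Cross-classified group grid
#'
#' Builds a group data.frame from the full crossing of grid dimensions
#' (e.g. survey year x gender x age band), with composite labels, suitable
#' for \code{\link{popSpec}}.
#'
#' @param ... named vectors of grid levels, e.g. \code{year = 2010:2019}.
#' @return data.frame with one row per cell and a \code{label} column.
#' @examples
#' makeGroupGrid(year = 2010:2013, gender = c("boys", "girls"))
#' @export
makeGroupGrid <- function(...) {
  dims <- list(...)
  if (!length(dims) || is.null(names(dims)) || any(names(dims) == ""))
    stop("supply named grid dimensions")
  g <- expand.grid(rev(dims), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(dims)), drop = FALSE]
  g$label <- do.call(paste, c(lapply(g, as.character), sep = "."))
  g[, c("label", names(dims))]
}

#' DMI-like generating specification
#'
#' A convenience preset emulating the study conditions of a six-item,
#' four-category depressive-symptom inventory measured across survey years,
#' genders and age bands: loadings spread over 0.65-0.86, one correlated
#' residual pair (items 3-4), right-skewed thresholds, and 5\% MCAR
#' item-level missingness.
#'
#' @param years,genders,ages grid levels (defaults: 10 years x 2 genders x
#'   5 age bands).
#' @param n per-group sample size(s).
#' @param missRate item-level missingness rate.
#' @return a \linkS4class{PopulationSpec}.
#' @export
dmiSpec <- function(years = 2010:2019, genders = c("boys", "girls"),
                    ages = 13:17, n = 1000, missRate = 0.05) {
  grid <- makeGroupGrid(year = years, gender = genders, age = ages)
  popSpec(groups = grid, n = n,
          lambda = c(0.67, 0.72, 0.85, 0.83, 0.74, 0.80),
          residualPairs = rbind(c(3L, 4L)), rho = 0.25,
          missRate = missRate)
}

#' Inject noninvariance into a population specification
#'
#' Returns a new spec differing only in the named parameter for the target
#' groups; the injection is recorded in the spec's provenance log. An
#' intercept shift on the latent response is equivalent to shifting all
#' thresholds of the item by the opposite sign; both entry points are
#' provided.
#'
#' @param spec a \linkS4class{PopulationSpec}.
#' @param item item index.
#' @param parameter one of \code{"threshold"}, \code{"loading"},
#'   \code{"intercept"}.
#' @param shift real shift; for \code{"threshold"} either a scalar (location
#'   shift of all C-1 thresholds) or a length C-1 vector.
#' @param targetGroups group labels (or indices) to modify.
#' @return a new \linkS4class{PopulationSpec}.
#' @export
injectNoninvariance <- function(spec, item, parameter = c("threshold", "loading", "intercept"),
                                shift, targetGroups) {
  parameter <- match.arg(parameter)
  K <- length(spec@items)
  if (item < 1L || item > K) stop("item index out of range")
  labs <- spec@groupInfo$label
  if (is.numeric(targetGroups)) targetGroups <- labs[targetGroups]
  if (!all(targetGroups %in% labs))
    stop("unknown target group(s): ", paste(setdiff(targetGroups, labs), collapse = ", "))
  for (g in targetGroups) {
    p <- spec@params[[g]]
    if (parameter == "loading") {
      newLam <- p$lambda[item] + shift
      if (newLam <= 0) stop(sprintf("loading shift makes lambda <= 0 for item %d", item))
      p$lambda[item] <- newLam
      ## keep the residual variance, so Var(y*) changes with the loading
    } else if (parameter == "intercept") {
      p$nu[item] <- p$nu[item] + shift
    } else {
      sh <- if (length(shift) == 1L) rep(shift, ncol(p$tau)) else shift
      if (length(sh) != ncol(p$tau)) stop("threshold shift must be scalar or length C-1")
      newTau <- p$tau[item, ] + sh
      if (any(diff(newTau) <= 0))
        stop(sprintf("threshold shift makes thresholds non-monotone for item %d", item))
      p$tau[item, ] <- newTau
    }
    spec@params[[g]] <- p
  }
  spec@injections <- rbind(spec@injections,
                           data.frame(item = item, parameter = parameter,
                                      shift = mean(shift), group = targetGroups,
                                      stringsAsFactors = FALSE))
  validObject(spec)
  spec
}

#' Serialize a population specification to YAML
#'
#' @param spec a \linkS4class{PopulationSpec}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSpec <- function(spec, path) {
  x <- list(
    items = spec@items, nCategories = spec@nCategories,
    groupInfo = as.list(spec@groupInfo),
    residualPairs = if (nrow(spec@residualPairs)) t(spec@residualPairs) else NULL,
    missRate = spec@missRate, missMode = spec@missMode, marSlope = spec@marSlope,
    params = lapply(spec@params, function(p)
      list(kappa = p$kappa, phi = p$phi, lambda = p$lambda, nu = p$nu,
           tau = t(p$tau), theta = p$theta, rho = p$rho)))
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' Read a population specification from YAML
#'
#' @param path file written by \code{\link{writeSpec}}.
#' @return a \linkS4class{PopulationSpec}.
#' @export
readSpec <- function(path) {
  x <- yaml::read_yaml(path)
  K <- length(x$items); C <- as.integer(x$nCategories)
  gi <- as.data.frame(x$groupInfo, stringsAsFactors = FALSE)
  rp <- if (is.null(x$residualPairs)) NULL else matrix(unlist(x$residualPairs), ncol = 2L, byrow = TRUE)
  G <- nrow(gi)
  lam <- sapply(x$params, function(p) p$lambda)
  nuM <- sapply(x$params, function(p) p$nu)
  thetaM <- sapply(x$params, function(p) p$theta)
  tauL <- lapply(x$params, function(p) matrix(unlist(p$tau), K, C - 1L, byrow = TRUE))
  rhoM <- if (!is.null(rp)) sapply(x$params, function(p) p$rho) else NULL
  if (!is.null(rhoM) && !is.matrix(rhoM)) rhoM <- matrix(rhoM, nrow = nrow(rp))
  popSpec(groups = gi[, setdiff(names(gi), c("n", "nClusters", "clusterSd")), drop = FALSE],
          n = gi$n, nItems = K, nCategories = C,
          lambda = lam, kappa = as.numeric(sapply(x$params, `[[`, "kappa")),
          phi = as.numeric(sapply(x$params, `[[`, "phi")), nu = nuM,
          tau = tauL, theta = thetaM, residualPairs = rp,
          rho = if (is.null(rhoM)) 0 else rhoM,
          missRate = x$missRate, missMode = x$missMode, marSlope = x$marSlope,
          nClusters = if (is.null(gi$nClusters)) 0L else gi$nClusters,
          clusterSd = if (is.null(gi$clusterSd)) 0 else gi$clusterSd)
}
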