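## Simulation from the one-factor normal-ogive model.

## Deterministic child seed for group i under root seed s (kept < 2^31).
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 2099 + i * 7919 + 1) %% 2147483647L
}

#' Simulate an ordinal multi-group dataset
#'
#' Draws, for each respondent in group g, a latent trait
#' \eqn{\eta \sim N(\kappa_g, \phi_g)} (plus an optional cluster-level shift),
#' residuals from the group's residual covariance, forms the latent responses
#' \eqn{y^*_j = \nu_j + \lambda_j \eta + \epsilon_j} and thresholds them into
#' categories \eqn{1..C}. Item cells are then set missing (MCAR by default;
#' optionally MAR with missingness probability increasing in \eqn{\eta}).
#' Each group uses its own child random stream derived from the root seed,
#' so adding a group does not perturb the others.
#'
#' @param spec a \linkS4class{PopulationSpec}.
#' @param seed integer root seed.
#' @return an \linkS4class{OrdinalDataset}.
#' @examples
#' d <- simulateOrdinal(popSpec(groups = c("a", "b"), n = 200), seed = 1)
#' table(responses(d)[, 1], useNA = "ifany")
#' @export
simulateOrdinal <- function(spec, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  validObject(spec)
  K <- length(spec@items); C <- spec@nCategories
  G <- nrow(spec@groupInfo)
  out <- vector("list", G)
  clusterIds <- vector("list", G)
  gridCols <- setdiff(names(spec@groupInfo), c("n", "nClusters", "clusterSd"))
  for (g in seq_len(G)) {
    info <- spec@groupInfo[g, ]
    p <- spec@params[[g]]
    n <- info$n
    set.seed(.childSeed(seed, g))
    eta <- stats::rnorm(n, p$kappa, sqrt(p$phi))
    cl <- NULL
    if (!is.null(info$nClusters) && info$nClusters > 0L) {
      cid <- sample.int(info$nClusters, n, replace = TRUE)
      eta <- eta + stats::rnorm(info$nClusters, 0, info$clusterSd)[cid]
      cl <- paste0(info$label, ".c", cid)
    }
    Th <- .residCov(spec, g)
    Lch <- tryCatch(chol(Th), error = function(e)
      stop(sprintf("residual covariance not positive definite in group '%s'", info$label)))
    eps <- matrix(stats::rnorm(n * K), n, K) %*% Lch
    ystar <- matrix(p$nu, n, K, byrow = TRUE) +
      outer(eta, p$lambda) + eps
    y <- matrix(1L, n, K)
    for (j in seq_len(K)) for (cc in seq_len(C - 1L))
      y[, j] <- y[, j] + (ystar[, j] > p$tau[j, cc])
    if (spec@missRate > 0) {
      if (spec@missMode == "MCAR") {
        pm <- matrix(spec@missRate, n, K)
      } else {
        ## MAR in eta: logistic with intercept calibrated to the target rate
        pm <- matrix(stats::plogis(stats::qlogis(spec@missRate) +
                                     spec@marSlope * (eta - p$kappa) / sqrt(p$phi)),
                     n, K)
      }
      y[matrix(stats::runif(n * K), n, K) < pm] <- NA_integer_
    }
    out[[g]] <- y
    clusterIds[[g]] <- if (is.null(cl)) rep(NA_character_, n) else cl
  }
  items <- do.call(rbind, out)
  colnames(items) <- spec@items
  groups <- spec@groupInfo[rep(seq_len(G), spec@groupInfo$n), gridCols, drop = FALSE]
  rownames(groups) <- NULL
  cl <- unlist(clusterIds)
  if (all(is.na(cl))) cl <- NULL
  new("OrdinalDataset", items = items, groups = groups, cluster = cl,
      nCategories = C, seed = as.integer(seed))
}

#' Analytic category probabilities of one item
#'
#' Normal-ogive marginal probabilities
#' \eqn{P(Y = c) = \Phi((\tau_c - \mu)/s) - \Phi((\tau_{c-1} - \mu)/s)} with
#' \eqn{\mu = \nu + \lambda\kappa} and \eqn{s = \sqrt{\lambda^2\phi + \theta}}.
#' Used as the closed-form oracle for the simulator.
#'
#' @param tau thresholds (length C-1).
#' @param lambda,nu,theta item parameters.
#' @param kappa,phi latent mean and variance.
#' @return probability vector of length C.
#' @export
categoryProbs <- function(tau, lambda, nu = 0, theta = 1 - lambda^2,
                          kappa = 0, phi = 1) {
  mu <- nu + lambda * kappa
  s <- sqrt(lambda^2 * phi + theta)
  pc <- stats::pnorm(c(tau, Inf), mu, s) - stats::pnorm(c(-Inf, tau), mu, s)
  as.numeric(pc)
}

## group slice of the response matrix for a given label of grouping column(s)
.groupFactor <- function(dataset, grouping = "label") {
  gd <- dataset@groups
  miss <- setdiff(grouping, names(gd))
  if (length(miss)) stop("unknown grouping column(s): ", paste(miss, collapse = ", "))
  if (length(grouping) == 1L) factor(gd[[grouping]], levels = unique(gd[[grouping]]))
  else {
    lab <- do.call(paste, c(lapply(gd[grouping], as.character), sep = "."))
    factor(lab, levels = unique(lab))
  }
}
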