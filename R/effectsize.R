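## d_MACS: observed-score effect size of item-level noninvariance.

#' Expected item score given the latent trait
#'
#' \eqn{E[Y|\eta] = \sum_c c\,[\Phi((\tau_c - \nu - \lambda\eta)/\sqrt\theta)
#' - \Phi((\tau_{c-1} - \nu - \lambda\eta)/\sqrt\theta)]} with
#' \eqn{\tau_0 = -\infty}, \eqn{\tau_C = +\infty}. Vectorized over \code{eta}.
#'
#' @param eta latent trait value(s).
#' @param tau thresholds (length C-1).
#' @param lambda,nu item loading and latent-response intercept.
#' @param theta residual variance (> 0).
#' @return numeric vector of expected category scores.
#' @export
expectedItemScore <- function(eta, tau, lambda, nu = 0, theta = 1 - lambda^2) {
  if (theta <= 0) stop("residual variance theta must be > 0")
  s <- sqrt(theta)
  C <- length(tau) + 1L
  ## E[Y|eta] = C - sum_c Phi((tau_c - nu - lambda eta)/s)
  out <- rep(C, length(eta))
  for (cc in seq_along(tau))
    out <- out - stats::pnorm((tau[cc] - nu - lambda * eta) / s)
  out
}

## model-implied observed mean and variance of an item under N(kappa, phi)
.itemMoments <- function(par, kappa, phi, nodes) {
  gh <- .ghNodes(nodes)
  eta <- kappa + sqrt(2 * phi) * gh$x
  w <- gh$w / sqrt(pi)
  s <- sqrt(par$theta)
  C <- length(par$tau) + 1L
  ## category probabilities at each node
  cum <- vapply(par$tau, function(tc)
    stats::pnorm((tc - par$nu - par$lambda * eta) / s), numeric(length(eta)))
  cum <- cbind(cum, 1)
  pc <- cum - cbind(0, cum[, -C, drop = FALSE])
  ey <- as.numeric(pc %*% seq_len(C))
  ey2 <- as.numeric(pc %*% (seq_len(C)^2))
  list(mean = sum(w * ey), var = sum(w * ey2) - sum(w * ey)^2)
}

.ghNodes <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.ordinvar_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    .ordinvar_cache[[key]] <- list(x = gh$x, w = gh$w)
  }
  .ordinvar_cache[[key]]
}

#' d_MACS effect size of noninvariance for one item
#'
#' Root integrated squared difference in expected item scores between a focal
#' and a reference group, weighted by the reference group's latent
#' distribution and scaled by a pooled observed-score SD:
#' \deqn{d = \sqrt{\int (E_F[Y|\eta] - E_R[Y|\eta])^2\, N(\eta;\kappa_R,
#' \phi_R)\, d\eta} \;/\; SD_{pooled}}
#' evaluated by Gauss-Hermite quadrature with a node-doubling convergence
#' check. The pooled SD defaults to the square root of the average of the
#' two groups' model-implied observed item variances, each computed under its
#' own latent distribution. Swapping reference and focal groups may change d
#' (the reference distribution weights the integral); that asymmetry is
#' intrinsic to the measure.
#'
#' @param paramsRef,paramsFocal lists with \code{tau}, \code{lambda},
#'   \code{nu}, \code{theta} for the reference and focal group.
#' @param latentRef \code{c(kappa, phi)} of the reference group's latent
#'   distribution.
#' @param latentFocal latent distribution of the focal group (used only for
#'   the pooled SD; defaults to \code{latentRef}).
#' @param pooledSd optional externally supplied pooled observed-score SD.
#' @param nodes Gauss-Hermite node count (doubled for the convergence check).
#' @param item optional item label carried into the result.
#' @return data.frame of class \code{DmacsResult}: item, d, pooledSd, nodes,
#'   band (negligible < 0.2 <= small < 0.4 <= medium < 0.7 <= large).
#' @examples
#' p <- list(tau = c(-0.674, 0, 0.674), lambda = 0.8, nu = 0, theta = 0.36)
#' pf <- p; pf$nu <- 0.3
#' dmacs(p, pf)
#' @export
dmacs <- function(paramsRef, paramsFocal, latentRef = c(0, 1),
                  latentFocal = latentRef, pooledSd = NULL, nodes = 50L,
                  item = NA_character_) {
  for (p in list(paramsRef, paramsFocal)) {
    if (p$theta <= 0) stop("residual variance theta must be > 0")
    if (length(p$tau) > 1L && any(diff(p$tau) <= 0)) stop("thresholds must be increasing")
  }
  kR <- latentRef[1]; pR <- latentRef[2]
  integral <- function(n) {
    gh <- .ghNodes(n)
    eta <- kR + sqrt(2 * pR) * gh$x
    w <- gh$w / sqrt(pi)
    dif <- expectedItemScore(eta, paramsFocal$tau, paramsFocal$lambda,
                             paramsFocal$nu, paramsFocal$theta) -
      expectedItemScore(eta, paramsRef$tau, paramsRef$lambda,
                        paramsRef$nu, paramsRef$theta)
    sum(w * dif^2)
  }
  i1 <- integral(nodes)
  i2 <- integral(2L * nodes)
  if (abs(i2 - i1) > 1e-4 * max(abs(i2), 1e-12) && abs(i2 - i1) > 1e-12)
    stop("quadrature did not converge under node doubling; increase 'nodes'")
  if (is.null(pooledSd)) {
    vR <- .itemMoments(paramsRef, kR, pR, 2L * nodes)$var
    vF <- .itemMoments(paramsFocal, latentFocal[1], latentFocal[2], 2L * nodes)$var
    pooledSd <- sqrt((vR + vF) / 2)
  }
  if (pooledSd <= 0) stop("pooled SD must be > 0")
  d <- sqrt(i2) / pooledSd
  band <- cut(d, c(-Inf, 0.2, 0.4, 0.7, Inf),
              labels = c("negligible", "small", "medium", "large"), right = FALSE)
  structure(data.frame(item = item, d = d, pooledSd = pooledSd,
                       nodes = 2L * nodes, band = as.character(band),
                       stringsAsFactors = FALSE),
            class = c("DmacsResult", "data.frame"))
}

## extract one group's item parameter list from a CfaFit
.itemParams <- function(fit, group, item) {
  est <- fit@estimates
  sub <- est[est$group == group, ]
  tau <- sub$est[sub$type == "tau" & sub$item == item]
  tau <- tau[order(sub$cat[sub$type == "tau" & sub$item == item])]
  lambda <- sub$est[sub$type == "lambda" & sub$item == item]
  nu <- sub$est[sub$type == "nu" & sub$item == item]
  psi <- sub$est[sub$type == "psi" & sub$item == item]
  phi <- sub$est[sub$type == "phi"]
  list(tau = tau, lambda = lambda, nu = nu,
       theta = max(psi - lambda^2 * phi, 1e-6),
       kappa = sub$est[sub$type == "kappa"], phi = phi)
}

#' d_MACS table across groups from a fitted multigroup model
#'
#' Computes, for every item and every non-reference group, the d_MACS effect
#' size against a fixed reference group, using the fitted group parameters
#' and the reference group's estimated latent distribution.
#'
#' @param fit a multigroup \linkS4class{CfaFit}. Use a model that separates
#'   latent means from item parameters (scalar or partial-scalar): in a
#'   configural fit, true latent-mean differences are absorbed into the
#'   group thresholds and would be misread as item noninvariance.
#' @param reference reference group label (default: first group).
#' @param nodes Gauss-Hermite node count.
#' @return data.frame: item, group, d, band.
#' @export
dmacsTable <- function(fit, reference = NULL, nodes = 50L) {
  groups <- fit@model@groups
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("unknown reference group")
  K <- length(fit@model@items)
  out <- list()
  for (g in setdiff(groups, reference)) {
    for (j in seq_len(K)) {
      pR <- .itemParams(fit, reference, j)
      pF <- .itemParams(fit, g, j)
      r <- dmacs(pR, pF, latentRef = c(pR$kappa, pR$phi),
                 latentFocal = c(pF$kappa, pF$phi), nodes = nodes,
                 item = fit@model@items[j])
      out[[length(out) + 1L]] <- data.frame(item = fit@model@items[j],
                                            group = g, d = r$d, band = r$band,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
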