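## DWLS estimation (WLSMV-style): minimize
##   F = sum_g n_g (s_g - sigma_g)' W_g^{-1} (s_g - sigma_g),  W_g = diag(Gamma_g)
## by damped Gauss-Newton with analytic Jacobians. Robust mean-and-variance
## adjusted (scaled-and-shifted) test statistic and sandwich standard errors
## use the full influence-function covariance Gamma_g.

.momentVector <- function(m) {
  K <- length(m@items)
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  c(unlist(m@thresholds), m@rho[pairs])
}

#' Fit a one-factor ordinal CFA by diagonally weighted least squares
#'
#' @param moments a \linkS4class{PolychoricMoments}, a list of them (one per
#'   group), or an \linkS4class{OrdinalDataset} (moments are then computed
#'   per group of \code{grouping}).
#' @param model a \linkS4class{CfaModel}; if NULL, a configural model with
#'   \code{residualPairs} is built.
#' @param grouping grouping column(s) when \code{moments} is a dataset.
#' @param residualPairs residual pairs for the default model.
#' @param start optional start vector (optimization scale).
#' @param warmFrom optional previous \linkS4class{CfaFit} whose estimates
#'   seed the start values.
#' @param maxit maximum Gauss-Newton iterations.
#' @param checkIdentification verify the Jacobian has full column rank at the
#'   start values.
#' @return a \linkS4class{CfaFit}.
#' @export
fitCfa <- function(moments, model = NULL, grouping = "label",
                   residualPairs = NULL, start = NULL, warmFrom = NULL,
                   maxit = 300L, checkIdentification = TRUE) {
  if (is(moments, "OrdinalDataset"))
    moments <- polyMomentsByGroup(moments, grouping = grouping)
  if (is(moments, "PolychoricMoments")) moments <- list(moments)
  if (is.null(model))
    model <- cfaModel(moments, level = "configural", residualPairs = residualPairs)
  G <- length(moments)
  if (G != length(model@groups)) stop("model and moments disagree on group count")
  ix <- .modelIndex(model, moments)
  sVec <- unlist(lapply(moments, .momentVector))
  nG <- vapply(moments, function(m) as.numeric(m@n), numeric(1))
  M <- length(sVec)
  wDiag <- unlist(lapply(moments, function(m) diag(m@acov)))
  sqrtn <- rep(sqrt(nG), each = ix$Mg)
  wInv <- 1 / wDiag
  sw <- sqrtn * sqrt(wInv)        # row scaling: residuals and Jacobian

  x <- if (!is.null(start)) start else .startValues(model, ix, moments)
  if (!is.null(warmFrom)) x <- .warmStart(model, ix, warmFrom, x)

  if (checkIdentification) {
    J0 <- .sigma(model, ix, x, jacobian = TRUE)$J
    if (qr(J0 * sw)$rank < ix$npar)
      stop("model not identified: Jacobian rank ", qr(J0 * sw)$rank,
           " < ", ix$npar, " free parameters")
  }

  objF <- function(x) {
    sg <- .sigma(model, ix, x)
    sum((sw * (sVec - sg$sigma))^2)
  }
  ## damped Gauss-Newton
  sg <- .sigma(model, ix, x, jacobian = TRUE)
  rw <- sw * (sVec - sg$sigma)
  Fcur <- sum(rw^2)
  damp <- 1e-8
  iter <- 0L
  converged <- FALSE
  gradNorm <- Inf
  repeat {
    iter <- iter + 1L
    Jw <- sg$J * sw
    g <- crossprod(Jw, rw)         # = -grad/2
    gradNorm <- max(abs(2 * g))
    A <- crossprod(Jw)
    ok <- FALSE
    for (tries in 1:25) {
      step <- tryCatch(solve(A + damp * diag(diag(A) + 1e-10), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        xNew <- x + as.numeric(step)
        Fnew <- objF(xNew)
        if (is.finite(Fnew) && Fnew <= Fcur + 1e-12) { ok <- TRUE; break }
      }
      damp <- damp * 10
    }
    if (!ok) break
    relChange <- (Fcur - Fnew) / max(Fcur, 1e-10)
    x <- xNew
    sg <- .sigma(model, ix, x, jacobian = TRUE)
    rw <- sw * (sVec - sg$sigma)
    Fcur <- sum(rw^2)
    damp <- max(damp / 10, 1e-10)
    g <- crossprod(sg$J * sw, rw)
    gradNorm <- max(abs(2 * g))
    if ((relChange < 1e-10 && gradNorm < 1e-6) || relChange < 1e-14) {
      converged <- TRUE; break
    }
    if (iter >= maxit) break
  }
  if (!converged && gradNorm > 1e-3)
    warning(sprintf("optimizer did not fully converge (gradient norm %.2e after %d iterations)",
                    gradNorm, iter))

  ## ---- robust statistics -----------------------------------------------
  J <- sg$J
  Dn <- sqrtn
  Jbar <- J * Dn
  V <- wInv                             # diagonal of V
  Gam <- matrix(0, M, M)
  for (g2 in seq_len(G)) {
    idx <- (g2 - 1L) * ix$Mg + seq_len(ix$Mg)
    Gam[idx, idx] <- moments[[g2]]@acov
  }
  A <- crossprod(Jbar * sqrt(V))
  Ainv <- tryCatch(solve(A), error = function(e) .pseudoInverse(A))
  VJ <- Jbar * V                        # V %*% Jbar (diagonal V)
  ## U = V - V J (J'VJ)^-1 J'V   (V diagonal)
  UGam <- V * Gam - VJ %*% (Ainv %*% (t(VJ) %*% Gam))
  tr1 <- sum(diag(UGam))
  tr2 <- sum(UGam * t(UGam))
  df <- M - ix$npar
  Tstat <- Fcur
  if (df > 0) {
    a <- sqrt(df / tr2)
    chisq <- max(a * Tstat + (df - a * tr1), 0)
    chisqMean <- df / tr1 * Tstat
  } else {
    chisq <- chisqMean <- 0
  }
  vcov <- Ainv %*% (t(VJ) %*% Gam %*% VJ) %*% Ainv

  ## ---- baseline (null) model: free thresholds, zero correlations --------
  nThrTot <- sum(ix$nThr)
  corrIdx <- as.vector(vapply(seq_len(G), function(g2)
    (g2 - 1L) * ix$Mg + nThrTot + seq_len(ix$Mg - nThrTot), integer(ix$Mg - nThrTot)))
  Tb <- sum((sw[corrIdx] * sVec[corrIdx])^2)
  dfb <- length(corrIdx)
  ## U_b Gamma restricted to the correlation block (thresholds fit exactly)
  UGb <- V[corrIdx] * Gam[corrIdx, corrIdx, drop = FALSE]
  tr1b <- sum(diag(UGb))
  tr2b <- sum(UGb * t(UGb))
  ab <- sqrt(dfb / tr2b)
  chisqB <- max(ab * Tb + (dfb - ab * tr1b), 0)

  N <- sum(nG)
  fi <- fitIndices(chisq, df, chisqB, dfb, N, G)
  ## SRMR over residual polychoric correlations (thresholds excluded)
  srmr <- sqrt(mean((sVec[corrIdx] - sg$sigma[corrIdx])^2))
  fi <- c(fi, srmr = srmr)

  ## ---- estimate table ----------------------------------------------------
  tpl <- model@template
  vOpt <- tpl$value
  vOpt[tpl$free] <- x[tpl$par[tpl$free]]
  est <- vOpt
  se <- rep(NA_real_, nrow(tpl))
  parSe <- sqrt(pmax(diag(vcov), 0))
  isLog <- tpl$type %in% c("logphi", "logpsi")
  est[isLog] <- exp(vOpt[isLog])
  fr <- tpl$free
  se[fr] <- parSe[tpl$par[fr]]
  se[fr & isLog] <- se[fr & isLog] * est[fr & isLog]
  estimates <- data.frame(
    type = sub("^log", "", tpl$type), item = tpl$item, cat = tpl$cat,
    pair = tpl$pair, group = model@groups[tpl$group], free = tpl$free,
    est = est, se = se, opt = vOpt, par = tpl$par, stringsAsFactors = FALSE)

  ## Heywood check: implied residual variance psi - lambda^2 phi per item
  heywood <- character(0)
  for (g2 in seq_len(G)) {
    sub <- estimates[estimates$group == model@groups[g2], ]
    lam <- sub$est[sub$type == "lambda"][order(sub$item[sub$type == "lambda"])]
    psi <- sub$est[sub$type == "psi"][order(sub$item[sub$type == "psi"])]
    phi <- sub$est[sub$type == "phi"]
    bad <- which(psi - lam^2 * phi < 0)
    if (length(bad))
      heywood <- c(heywood, sprintf("group %s item %d", model@groups[g2], bad))
  }
  if (length(heywood))
    warning("inadmissible solution (negative implied residual variance): ",
            paste(heywood, collapse = "; "))

  fit <- new("CfaFit", model = model, estimates = estimates, theta = as.numeric(x),
             vcov = vcov, F = Fcur, chisq = chisq, chisqMean = chisqMean,
             df = as.numeric(df),
             indices = fi, baseline = c(chisq = chisqB, df = dfb),
             nObs = nG, converged = converged,
             diagnostics = list(iterations = iter, gradNorm = gradNorm,
                                heywood = heywood, tr1 = tr1, tr2 = tr2,
                                statistic = "scaled-shifted"))
  fit
}

## minimal generalized inverse fallback (no MASS dependency)
.pseudoInverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit indices from test statistics
#'
#' CFI, TLI and RMSEA (with 90\% CI from the noncentral chi-square) computed
#' from a target and a baseline test statistic. The multigroup RMSEA
#' multiplies the per-group noncentrality form by \eqn{\sqrt{G}}:
#' \eqn{RMSEA = \sqrt{G}\sqrt{\max(\chi^2 - df, 0)/(df\,(N - G))}}.
#'
#' @param chisq,df target model statistic and degrees of freedom.
#' @param baselineChisq,baselineDf baseline (null) model statistic and df.
#' @param nTotal total sample size.
#' @param nGroups number of groups G.
#' @return named numeric: cfi, tli, rmsea, rmsea.lo, rmsea.hi.
#' @examples
#' fitIndices(200, 50, 5000, 15, 1000, 1)
#' @export
fitIndices <- function(chisq, df, baselineChisq, baselineDf, nTotal, nGroups = 1) {
  d <- max(chisq - df, 0)
  db <- max(baselineChisq - baselineDf, 0)
  cfi <- 1 - d / max(db, d, .Machine$double.eps)
  tli <- if (df > 0 && baselineDf > 0 && baselineChisq / baselineDf > 1) {
    min(((baselineChisq / baselineDf) - (chisq / df)) /
          ((baselineChisq / baselineDf) - 1), 1)
  } else 1
  denom <- df * (nTotal - nGroups)
  rmsea <- if (df > 0) sqrt(nGroups) * sqrt(d / denom) else 0
  ci <- .rmseaCI(chisq, df, nTotal, nGroups)
  c(cfi = cfi, tli = tli, rmsea = rmsea, rmsea.lo = ci[1], rmsea.hi = ci[2])
}

## 90% RMSEA CI by inverting the noncentral chi-square distribution
.rmseaCI <- function(chisq, df, N, G) {
  if (df <= 0 || !is.finite(chisq)) return(c(0, 0))
  denom <- df * (N - G)
  upperNcp <- function(target) {
    ## find ncp with pchisq(chisq, df, ncp) = target
    if (stats::pchisq(chisq, df) < target) return(0)
    f <- function(l) stats::pchisq(chisq, df, ncp = l) - target
    hi <- max(chisq * 2, df + 10)
    while (f(hi) > 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  lo <- upperNcp(0.95)
  hi <- upperNcp(0.05)
  sqrt(G) * c(sqrt(lo / denom), sqrt(hi / denom))
}

#' Composite reliability (omega) of a one-factor model
#'
#' \eqn{\omega = (\Sigma\lambda)^2\phi / ((\Sigma\lambda)^2\phi + \Sigma\theta
#' + 2\Sigma \theta_{jk})} on the latent-response scale, where
#' \eqn{\theta_j = \psi_j - \lambda_j^2\phi} are the implied residual
#' variances and \eqn{\theta_{jk}} the residual covariances.
#'
#' @param fit a converged single-group \linkS4class{CfaFit}; alternatively
#'   supply \code{lambda} (plus optional \code{theta}, \code{phi},
#'   \code{residCov}) directly.
#' @param lambda,theta,phi,residCov direct parameter entry (used when
#'   \code{fit} is missing).
#' @return omega in [0, 1].
#' @examples
#' omegaReliability(lambda = rep(0.8, 6), theta = rep(0.36, 6))  # ~0.914
#' @export
omegaReliability <- function(fit, lambda, theta = NULL, phi = 1,
                             residCov = numeric(0)) {
  if (!missing(fit)) {
    if (length(fit@model@groups) != 1L)
      stop("omega is defined here for a single-group fit")
    if (!fit@converged) stop("fit did not converge")
    est <- fit@estimates
    lambda <- est$est[est$type == "lambda"][order(est$item[est$type == "lambda"])]
    psi <- est$est[est$type == "psi"][order(est$item[est$type == "psi"])]
    phi <- est$est[est$type == "phi"]
    theta <- psi - lambda^2 * phi
    residCov <- est$est[est$type == "thcov"]
  } else {
    if (is.null(theta)) theta <- 1 - lambda^2 * phi
  }
  if (any(theta < -1e-8)) stop("inadmissible residual variance (theta < 0)")
  common <- sum(lambda)^2 * phi
  common / (common + sum(pmax(theta, 0)) + 2 * sum(residCov))
}
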