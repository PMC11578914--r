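## One-factor ordinal CFA under the delta parameterization.
##
## Group-level parameters: thresholds tau_jc, loadings lambda_j, latent
## response intercepts nu_j, latent mean kappa and variance phi, latent
## response variances psi_j (delta scales, optimized on the log scale), and
## residual covariances for designated item pairs. Implied moments per group:
##   standardized threshold  t*_jc = (tau_jc - nu_j - lambda_j kappa)/sqrt(psi_j)
##   latent-response corr    P_jk  = (lambda_j lambda_k phi + thcov_jk)
##                                   / sqrt(psi_j psi_k)
##
## Identification schedule across invariance levels (reference group = first):
##   configural : tau, lambda free per group; nu = 0, kappa = 0, phi = psi = 1.
##   thresholds : tau equal across groups; nu and psi freed in non-reference
##                groups; kappa = 0, phi = 1.
##   loadings   : + lambda equal; phi freed in non-reference groups.
##   intercepts : + nu = 0 in all groups; kappa freed in non-reference groups.
## Items listed in freeItems revert the step's own parameter to its
## configural treatment (partial invariance).

.invarianceLevels <- c("configural", "thresholds", "loadings", "intercepts")

#' Construct a one-factor ordinal CFA model
#'
#' Builds the parameter template realizing the identification schedule of the
#' requested invariance level (see the package vignette). The per-item
#' threshold counts are taken from the supplied group moments, which must be
#' structurally identical across groups.
#'
#' @param moments a \linkS4class{PolychoricMoments} or list of them (one per
#'   group, in group order; first group is the reference).
#' @param level invariance level: \code{"configural"}, \code{"thresholds"},
#'   \code{"loadings"}, or \code{"intercepts"}.
#' @param residualPairs integer matrix (npairs x 2) of correlated-residual
#'   item pairs, or NULL.
#' @param freeItems named list of item indices freed per step, e.g.
#'   \code{list(intercepts = 6L)} (partial invariance).
#' @return a \linkS4class{CfaModel}.
#' @export
cfaModel <- function(moments, level = "configural", residualPairs = NULL,
                     freeItems = list()) {
  if (is(moments, "PolychoricMoments")) moments <- list(moments)
  level <- match.arg(level, .invarianceLevels)
  G <- length(moments)
  items <- moments[[1]]@items
  K <- length(items)
  nThr <- lengths(moments[[1]]@thresholds)
  for (g in seq_len(G))
    if (!identical(lengths(moments[[g]]@thresholds), nThr))
      stop("groups differ in category structure (collapsed categories); ",
           "cannot equate thresholds")
  if (is.null(residualPairs)) residualPairs <- matrix(integer(0), 0L, 2L)
  residualPairs <- matrix(as.integer(residualPairs), ncol = 2L)
  npairs <- nrow(residualPairs)
  groups <- vapply(moments, function(m) m@group, character(1), USE.NAMES = FALSE)
  lvlNum <- match(level, .invarianceLevels)
  fi <- function(step) {
    v <- freeItems[[step]]
    if (is.null(v)) integer(0) else as.integer(v)
  }

  rows <- list()
  add <- function(type, item, cat, pair, group, free, value, key) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, item = item, cat = cat, pair = pair, group = group,
      free = free, value = value, key = key, stringsAsFactors = FALSE)
  }
  for (g in seq_len(G)) {
    for (j in seq_len(K)) {
      tauFree <- lvlNum < 2L || j %in% fi("thresholds")
      for (cc in seq_len(nThr[j]))
        add("tau", j, cc, NA, g, TRUE, 0,
            if (tauFree) sprintf("tau.%d.%d.g%d", j, cc, g)
            else sprintf("tau.%d.%d", j, cc))
      lamFree <- lvlNum < 3L || j %in% fi("loadings")
      add("lambda", j, NA, NA, g, TRUE, 0.7,
          if (lamFree) sprintf("lambda.%d.g%d", j, g) else sprintf("lambda.%d", j))
      ## nu and psi only identified when the item's thresholds are equated
      itemHasSharedTau <- !tauFree
      nuFree <- itemHasSharedTau && g > 1L &&
        (lvlNum %in% 2:3 || (lvlNum == 4L && j %in% fi("intercepts")))
      add("nu", j, NA, NA, g, nuFree, 0, sprintf("nu.%d.g%d", j, g))
      psiFree <- itemHasSharedTau && g > 1L && lvlNum >= 2L
      add("logpsi", j, NA, NA, g, psiFree, 0, sprintf("logpsi.%d.g%d", j, g))
    }
    add("kappa", NA, NA, NA, g, lvlNum == 4L && g > 1L, 0, sprintf("kappa.g%d", g))
    add("logphi", NA, NA, NA, g, lvlNum >= 3L && g > 1L, 0, sprintf("logphi.g%d", g))
    if (npairs) for (i in seq_len(npairs))
      add("thcov", NA, NA, i, g, TRUE, 0, sprintf("thcov.%d.g%d", i, g))
  }
  template <- do.call(rbind, rows)
  freeKeys <- unique(template$key[template$free])
  template$par <- ifelse(template$free, match(template$key, freeKeys), 0L)
  template$key <- NULL
  new("CfaModel", items = items, nCategories = max(nThr) + 1L,
      groups = groups, residualPairs = residualPairs, level = level,
      freeItems = freeItems, template = template)
}

## ---- internal index cache for fast evaluation -------------------------------

.modelIndex <- function(model, moments) {
  G <- length(model@groups)
  K <- length(model@items)
  nThr <- lengths(moments[[1]]@thresholds)
  npairs <- nrow(model@residualPairs)
  pairsAll <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairsAll <- pairsAll[order(pairsAll[, 1], pairsAll[, 2]), , drop = FALSE]
  Mg <- sum(nThr) + nrow(pairsAll)
  tpl <- model@template
  idx <- vector("list", G)
  for (g in seq_len(G)) {
    rows <- which(tpl$group == g)
    sub <- tpl[rows, ]
    tauRows <- lapply(seq_len(K), function(j)
      rows[sub$type == "tau" & sub$item == j][order(sub$cat[sub$type == "tau" & sub$item == j])])
    idx[[g]] <- list(
      tauRows = tauRows,
      lamRows = vapply(seq_len(K), function(j) rows[sub$type == "lambda" & sub$item == j], 1L),
      nuRows = vapply(seq_len(K), function(j) rows[sub$type == "nu" & sub$item == j], 1L),
      kappaRow = rows[sub$type == "kappa"],
      phiRow = rows[sub$type == "logphi"],
      psiRows = vapply(seq_len(K), function(j) rows[sub$type == "logpsi" & sub$item == j], 1L),
      thcovRows = if (npairs) vapply(seq_len(npairs), function(i)
        rows[sub$type == "thcov" & sub$pair == i], 1L) else integer(0))
  }
  list(G = G, K = K, nThr = nThr, thrOffset = c(0L, cumsum(nThr)),
       pairsAll = pairsAll, Mg = Mg, idx = idx,
       npar = max(tpl$par), par = tpl$par, free = tpl$free)
}

## expand free vector x into the template value column
.expandValues <- function(model, ix, x) {
  v <- model@template$value
  v[ix$free] <- x[ix$par[ix$free]]
  v
}

## implied moment vector (and optionally the analytic Jacobian)
.sigma <- function(model, ix, x, jacobian = FALSE) {
  v <- .expandValues(model, ix, x)
  G <- ix$G; K <- ix$K
  sig <- numeric(G * ix$Mg)
  J <- if (jacobian) matrix(0, G * ix$Mg, ix$npar) else NULL
  par <- ix$par
  rp <- model@residualPairs
  rpKey <- if (nrow(rp)) paste(rp[, 1], rp[, 2]) else character(0)
  for (g in seq_len(G)) {
    id <- ix$idx[[g]]
    off <- (g - 1L) * ix$Mg
    lam <- v[id$lamRows]; nu <- v[id$nuRows]
    kap <- v[id$kappaRow]; phi <- exp(v[id$phiRow])
    s <- exp(0.5 * v[id$psiRows])
    for (j in seq_len(K)) {
      tr <- off + ix$thrOffset[j] + seq_len(ix$nThr[j])
      tau <- v[id$tauRows[[j]]]
      tstar <- (tau - nu[j] - lam[j] * kap) / s[j]
      sig[tr] <- tstar
      if (jacobian) {
        pTau <- par[id$tauRows[[j]]]
        for (cc in seq_along(tr)) if (pTau[cc] > 0L)
          J[tr[cc], pTau[cc]] <- J[tr[cc], pTau[cc]] + 1 / s[j]
        pNu <- par[id$nuRows[j]]
        if (pNu > 0L) J[tr, pNu] <- J[tr, pNu] - 1 / s[j]
        pLam <- par[id$lamRows[j]]
        if (pLam > 0L && kap != 0) J[tr, pLam] <- J[tr, pLam] - kap / s[j]
        pKap <- par[id$kappaRow]
        if (pKap > 0L) J[tr, pKap] <- J[tr, pKap] - lam[j] / s[j]
        pPsi <- par[id$psiRows[j]]
        if (pPsi > 0L) J[tr, pPsi] <- J[tr, pPsi] - 0.5 * tstar
      }
    }
    thc <- if (nrow(rp)) v[id$thcovRows] else numeric(0)
    for (i in seq_len(nrow(ix$pairsAll))) {
      j <- ix$pairsAll[i, 1]; k <- ix$pairsAll[i, 2]
      m <- off + sum(ix$nThr) + i
      ipair <- match(paste(j, k), rpKey)
      tc <- if (!is.na(ipair)) thc[ipair] else 0
      denom <- s[j] * s[k]
      Pjk <- (lam[j] * lam[k] * phi + tc) / denom
      sig[m] <- Pjk
      if (jacobian) {
        pLj <- par[id$lamRows[j]]; pLk <- par[id$lamRows[k]]
        if (pLj > 0L) J[m, pLj] <- J[m, pLj] + lam[k] * phi / denom
        if (pLk > 0L) J[m, pLk] <- J[m, pLk] + lam[j] * phi / denom
        pPhi <- par[id$phiRow]
        if (pPhi > 0L) J[m, pPhi] <- J[m, pPhi] + lam[j] * lam[k] * phi / denom
        if (!is.na(ipair)) {
          pTc <- par[id$thcovRows[ipair]]
          if (pTc > 0L) J[m, pTc] <- J[m, pTc] + 1 / denom
        }
        pPj <- par[id$psiRows[j]]; pPk <- par[id$psiRows[k]]
        if (pPj > 0L) J[m, pPj] <- J[m, pPj] - 0.5 * Pjk
        if (pPk > 0L) J[m, pPk] <- J[m, pPk] - 0.5 * Pjk
      }
    }
  }
  list(sigma = sig, J = J)
}

## start values from the group moments
.startValues <- function(model, ix, moments) {
  tpl <- model@template
  x <- numeric(ix$npar)
  filled <- logical(ix$npar)
  G <- ix$G; K <- ix$K
  ## average correlation matrix -> principal-factor loadings
  Pbar <- Reduce(`+`, lapply(moments, polychoricCor)) / G
  e <- eigen(Pbar, symmetric = TRUE)
  lamStart <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
  if (mean(lamStart) < 0) lamStart <- -lamStart
  lamStart <- pmin(pmax(lamStart, 0.2), 0.95)
  for (g in seq_len(G)) {
    id <- ix$idx[[g]]
    thr <- moments[[g]]@thresholds
    for (j in seq_len(K)) {
      pTau <- ix$par[id$tauRows[[j]]]
      sel <- pTau > 0L & !filled[pmax(pTau, 1L)]
      if (any(sel)) { x[pTau[sel]] <- thr[[j]][sel]; filled[pTau[sel]] <- TRUE }
      pLam <- ix$par[id$lamRows[j]]
      if (pLam > 0L && !filled[pLam]) { x[pLam] <- lamStart[j]; filled[pLam] <- TRUE }
    }
    rp <- model@residualPairs
    if (nrow(rp)) for (i in seq_len(nrow(rp))) {
      pTc <- ix$par[id$thcovRows[i]]
      if (pTc > 0L && !filled[pTc]) {
        j <- rp[i, 1]; k <- rp[i, 2]
        x[pTc] <- moments[[g]]@rho[j, k] - lamStart[j] * lamStart[k]
        filled[pTc] <- TRUE
      }
    }
  }
  x   # remaining (nu, kappa, logphi, logpsi) start at 0
}

## map a previous fit's optimization-scale values into a new model's start
.warmStart <- function(modelNew, ixNew, fitOld, x0) {
  tplO <- fitOld@model@template
  tplN <- modelNew@template
  keyO <- paste(tplO$type, tplO$item, tplO$cat, tplO$pair, tplO$group)
  vO <- tplO$value
  vO[tplO$free] <- fitOld@theta[tplO$par[tplO$free]]
  keyN <- paste(tplN$type, tplN$item, tplN$cat, tplN$pair, tplN$group)
  m <- match(keyN, keyO)
  x <- x0
  for (p in seq_len(ixNew$npar)) {
    rows <- which(tplN$par == p & tplN$free)
    vals <- vO[m[rows]]
    vals <- vals[!is.na(vals)]
    if (length(vals)) x[p] <- mean(vals)
  }
  x
}

#' Model-implied moments of one group
#'
#' Standardized thresholds, latent-response correlation matrix, and implied
#' category probabilities for one group of a one-factor ordinal CFA under the
#' delta parameterization.
#'
#' @param lambda loadings (length K).
#' @param tau thresholds: K x (C-1) matrix or list of per-item vectors.
#' @param nu latent-response intercepts (default 0).
#' @param kappa,phi latent mean and variance.
#' @param psi latent-response variances (delta scales, default 1).
#' @param residualPairs optional npairs x 2 matrix of item pairs.
#' @param residCov residual covariances, one per pair.
#' @return list with \code{thresholds} (list of standardized thresholds),
#'   \code{correlation} (K x K), and \code{categoryProbs} (list; each sums
#'   to 1).
#' @examples
#' m <- impliedMoments(lambda = c(0.8, 0.8), tau = rbind(0, 0))
#' m$correlation[1, 2]   # 0.64
#' @export
impliedMoments <- function(lambda, tau, nu = 0, kappa = 0, phi = 1, psi = 1,
                           residualPairs = NULL, residCov = numeric(0)) {
  K <- length(lambda)
  if (is.matrix(tau)) tau <- lapply(seq_len(K), function(j) tau[j, ])
  nu <- rep_len(nu, K); psi <- rep_len(psi, K)
  if (any(psi <= 0)) stop("implied latent-response variance <= 0 (inadmissible point)")
  if (phi <= 0) stop("latent variance must be > 0")
  s <- sqrt(psi)
  tstar <- lapply(seq_len(K), function(j) (tau[[j]] - nu[j] - lambda[j] * kappa) / s[j])
  P <- outer(lambda, lambda) * phi
  if (!is.null(residualPairs)) {
    residualPairs <- matrix(as.integer(residualPairs), ncol = 2L)
    for (i in seq_len(nrow(residualPairs))) {
      j <- residualPairs[i, 1]; k <- residualPairs[i, 2]
      P[j, k] <- P[k, j] <- P[j, k] + residCov[i]
    }
  }
  P <- P / outer(s, s)
  diag(P) <- 1
  probs <- lapply(tstar, function(tv) {
    pc <- stats::pnorm(c(tv, Inf)) - stats::pnorm(c(-Inf, tv))
    as.numeric(pc)
  })
  list(thresholds = tstar, correlation = P, categoryProbs = probs)
}
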