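# Fixtures are generated in code. dmiLikeSpec mirrors the study conditions
# the generator defaults emulate (six 4-category items, loadings spread over
# 0.65-0.86, one correlated residual pair, 5% MCAR missingness).

dmiLambda <- c(0.67, 0.72, 0.85, 0.83, 0.74, 0.80)
dmiPair <- rbind(c(3L, 4L))

dmiLikeSpec <- function(nGroups = 4, n = 2000, missRate = 0.05, ...) {
  popSpec(groups = paste0("g", seq_len(nGroups)), n = n, lambda = dmiLambda,
          residualPairs = dmiPair, rho = 0.25, missRate = missRate, ...)
}

# Exact population moments of a single group (identity weight matrix), for
# self-consistency fits: the estimator must reproduce the generating point.
exactMoments <- function(lambda, tau, residualPairs = NULL,
                         residCov = numeric(0), n = 10000L, group = "g1") {
  K <- length(lambda)
  im <- impliedMoments(lambda, tau, residualPairs = residualPairs,
                       residCov = residCov)
  M <- sum(lengths(im$thresholds)) + K * (K - 1) / 2
  new("PolychoricMoments", group = group, items = paste0("item_", seq_len(K)),
      thresholds = im$thresholds, rho = im$correlation,
      acov = diag(1, M), pairN = matrix(n, K, K), n = as.integer(n))
}

# Minimal CfaFit carrying just fit indices and df (for decision-rule tests).
fakeFit <- function(cfi, rmsea, df, chisq = 100) {
  mdl <- new("CfaModel", items = paste0("item_", 1:6), nCategories = 4L,
             groups = "g1", residualPairs = matrix(integer(0), 0, 2),
             level = "intercepts", freeItems = list(),
             template = data.frame())
  new("CfaFit", model = mdl, estimates = data.frame(), theta = numeric(0),
      vcov = matrix(0, 0, 0), F = chisq, chisq = chisq, chisqMean = chisq,
      df = df,
      indices = c(cfi = cfi, tli = cfi, rmsea = rmsea, rmsea.lo = 0,
                  rmsea.hi = rmsea, srmr = 0.01),
      baseline = c(chisq = 5000, df = 15), nObs = 1000,
      converged = TRUE, diagnostics = list())
}
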