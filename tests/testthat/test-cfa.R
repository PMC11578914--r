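# The DWLS estimator: implied moments, exact-moment self-consistency,
# brute-force oracle equivalence, index formulas, and bookkeeping.

test_that("implied moments follow the product rule and normalize", {
  m <- impliedMoments(lambda = c(0.8, 0.8), tau = rbind(c(-1, 0, 1), c(-1, 0, 1)))
  expect_equal(m$correlation[1, 2], 0.64, tolerance = 1e-12)
  m0 <- impliedMoments(lambda = rep(0, 3), tau = matrix(0, 3, 3),
                       residualPairs = rbind(c(1L, 2L)), residCov = 0.3)
  expect_equal(m0$correlation, matrix(c(1, 0.3, 0, 0.3, 1, 0, 0, 0, 1), 3),
               tolerance = 1e-12)
  m1 <- impliedMoments(lambda = c(0.7, 0.5), tau = rbind(c(-0.3, 0.6), c(0, 1)),
                       nu = c(0.2, -0.1), kappa = 0.3, phi = 1.4, psi = c(1.2, 0.9))
  for (p in m1$categoryProbs) expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(impliedMoments(lambda = 0.5, tau = rbind(0), psi = -1),
               "inadmissible")
})

test_that("fitting exact model-implied moments recovers the generating point", {
  lam <- dmiLambda
  tau <- matrix(rep(c(-0.5, 0.3, 1.2), each = 6), 6)
  mo <- exactMoments(lam, tau, residualPairs = dmiPair, residCov = 0.1)
  fit <- fitCfa(list(mo), cfaModel(list(mo), "configural", residualPairs = dmiPair))
  expect_lt(fit@F, 1e-8)
  est <- estimates(fit)
  expect_equal(est$est[est$type == "lambda"], lam, tolerance = 1e-4)
  expect_equal(est$est[est$type == "thcov"], 0.1, tolerance = 1e-4)
  expect_equal(matrix(est$est[est$type == "tau"], 6, 3, byrow = TRUE), tau,
               tolerance = 1e-4)
  expect_true(fit@converged)
})

test_that("DWLS solution matches a brute-force minimization (3-item oracle)", {
  spec <- popSpec(groups = "g1", n = 5000, nItems = 3L,
                  lambda = c(0.7, 0.8, 0.6))
  d <- simulateOrdinal(spec, seed = 13)
  mo <- polyMoments(d)
  fit <- fitCfa(list(mo))
  # independent re-implementation of the same fit function, minimized by
  # Nelder-Mead from a neutral start
  s <- c(unlist(thresholds(mo)), polychoricCor(mo)[upper.tri(diag(3))])
  w <- 1 / diag(mo@acov)
  # the fit function separates: thresholds enter only their own residuals, so
  # the brute-force optimum fixes them at the sample values and searches the
  # loadings by a dense grid followed by Nelder-Mead polish
  wc <- w[10:12]; sc <- s[10:12]
  objLam <- function(lam)
    sum(wc * (sc - c(lam[1] * lam[2], lam[1] * lam[3], lam[2] * lam[3]))^2)
  grid <- seq(0.2, 0.95, by = 0.025)
  best <- NULL; bestV <- Inf
  for (l1 in grid) for (l2 in grid) for (l3 in grid) {
    v <- objLam(c(l1, l2, l3))
    if (v < bestV) { bestV <- v; best <- c(l1, l2, l3) }
  }
  bf <- optim(best, objLam, method = "Nelder-Mead",
              control = list(maxit = 10000, reltol = 1e-15))
  est <- estimates(fit)
  expect_equal(est$est[est$type == "lambda"], bf$par, tolerance = 1e-3)
  expect_equal(est$est[est$type == "tau"], s[1:9], tolerance = 1e-3)
  expect_equal(fit@F, bf$value * mo@n, tolerance = max(1e-4, bf$value * mo@n * 0.01))
})

test_that("single-group loadings are recovered from simulated data", {
  spec <- popSpec(groups = "g1", n = 5000, lambda = dmiLambda)
  d <- simulateOrdinal(spec, seed = 19)
  fit <- fitCfa(polyMoments(d), cfaModel(polyMoments(d), "configural"))
  est <- estimates(fit)
  expect_true(all(abs(est$est[est$type == "lambda"] - dmiLambda) < 0.03))
})

test_that("configural fit is invariant to group order", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 3, n = 700), seed = 23)
  mos <- polyMomentsByGroup(d)
  f1 <- fitCfa(mos, cfaModel(mos, "configural", residualPairs = dmiPair))
  mos2 <- mos[c(3, 1, 2)]
  f2 <- fitCfa(mos2, cfaModel(mos2, "configural", residualPairs = dmiPair))
  expect_equal(f1@F, f2@F, tolerance = 1e-7)
  expect_equal(f1@indices, f2@indices, tolerance = 1e-6)
})

test_that("fit-index formulas evaluate exactly", {
  fi <- fitIndices(200, 50, 5000, 15, 1000, 1)
  expect_equal(unname(fi["rmsea"]), sqrt(150 / (50 * 999)), tolerance = 1e-10)
  expect_equal(unname(fi["cfi"]), 1 - 150 / 4985, tolerance = 1e-10)
  # perfect-fit guards
  fi0 <- fitIndices(40, 50, 5000, 15, 1000, 1)
  expect_equal(unname(fi0["rmsea"]), 0)
  expect_equal(unname(fi0["cfi"]), 1)
  expect_equal(unname(fi0["rmsea.lo"]), 0)
  # the 90% CI brackets the point estimate
  expect_true(fi["rmsea.lo"] <= fi["rmsea"] && fi["rmsea"] <= fi["rmsea.hi"])
})

test_that("omega follows its closed form", {
  expect_equal(omegaReliability(lambda = rep(0.8, 6), theta = rep(0.36, 6)),
               23.04 / 25.20, tolerance = 1e-10)
  expect_equal(omegaReliability(lambda = rep(1e-12, 6), theta = rep(1, 6)), 0,
               tolerance = 1e-12)
  expect_equal(omegaReliability(lambda = rep(0.8, 6), theta = rep(0, 6)), 1)
  expect_error(omegaReliability(lambda = rep(0.8, 6), theta = rep(-0.1, 6)),
               "inadmissible")
})

test_that("equality constraints add the expected degrees of freedom", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 3, n = 600, missRate = 0), seed = 3)
  mos <- polyMomentsByGroup(d)
  dfs <- vapply(c("configural", "thresholds", "loadings", "intercepts"),
                function(lv) fitCfa(mos, cfaModel(mos, lv, residualPairs = dmiPair),
                                    checkIdentification = FALSE)@df,
                numeric(1))
  G <- 3; K <- 6
  expect_equal(unname(diff(dfs)),
               c((G - 1) * K * (4 - 3),     # thresholds: net 1 constraint/item
                 (G - 1) * (K - 1),         # loadings
                 (G - 1) * (K - 1)))        # intercepts
})

test_that("an unidentified model is rejected by the rank check", {
  mo <- exactMoments(c(0.7, 0.7), rbind(c(-1, 0, 1), c(-1, 0, 1)))
  # two items, one factor: 2 loadings vs 1 correlation cannot be identified
  expect_error(fitCfa(list(mo), cfaModel(list(mo), "configural")),
               "not identified")
})
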