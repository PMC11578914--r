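# Latent trend centering, reference changes, freed-vs-fixed counterfactuals,
# ICC, and descriptives.

scalarFit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- dmiLikeSpec(nGroups = 4, n = 1500)
      spec@params$g3$kappa <- 0.2
      spec@params$g4$kappa <- 0.3
      d <- simulateOrdinal(spec, seed = 71)
      mos <- polyMomentsByGroup(d)
      cache <<- fitCfa(mos, cfaModel(mos, "intercepts", residualPairs = dmiPair))
    }
    cache
  }
})

test_that("the reference group is centered exactly with a zero-width interval", {
  tr <- latentTrend(scalarFit())
  expect_equal(tr$deviation[1], 0)
  expect_equal(tr$se[1], 0)
  expect_equal(tr$lower[1], 0)
  expect_equal(tr$upper[1], 0)
  expect_true(all(tr$upper - tr$deviation - (tr$deviation - tr$lower) < 1e-12))
  # deviations track the generating latent means
  expect_equal(tr$deviation, c(0, 0, 0.2, 0.3), tolerance = 0.12)
})

test_that("changing the reference preserves latent-mean differences exactly", {
  fit <- scalarFit()
  t1 <- latentTrend(fit, reference = "g1")
  t2 <- latentTrend(fit, reference = "g3")
  est <- estimates(fit)
  phiOf <- function(g) est$est[est$type == "phi" & est$group == g]
  # unstandardized deviations differ by the constant kappa_ref1 - kappa_ref2
  shift <- t2$deviation * sqrt(phiOf("g3")) - t1$deviation * sqrt(phiOf("g1"))
  expect_lt(diff(range(shift)), 1e-10)
})

test_that("latent means are refused below partial scalar invariance", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 2, n = 600), seed = 73)
  mos <- polyMomentsByGroup(d)
  conf <- fitCfa(mos, cfaModel(mos, "configural", residualPairs = dmiPair))
  expect_error(latentTrend(conf), "scalar")
})

test_that("trends are invariant to item relabeling", {
  spec <- dmiLikeSpec(nGroups = 3, n = 1200)
  spec@params$g3$kappa <- 0.25
  d <- simulateOrdinal(spec, seed = 79)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  y2 <- responses(d)[, perm]
  colnames(y2) <- paste0("item_", 1:6)
  d2 <- new("OrdinalDataset", items = y2, groups = groupData(d), cluster = NULL,
            nCategories = 4L, seed = 79L)
  pairPerm <- matrix(match(c(3L, 4L), perm), 1)  # items 3,4 under new labels
  mos <- polyMomentsByGroup(d)
  mos2 <- polyMomentsByGroup(d2)
  f1 <- fitCfa(mos, cfaModel(mos, "intercepts", residualPairs = dmiPair))
  f2 <- fitCfa(mos2, cfaModel(mos2, "intercepts",
                              residualPairs = t(apply(pairPerm, 1, sort))))
  expect_equal(latentTrend(f1)$deviation, latentTrend(f2)$deviation,
               tolerance = 1e-5)
})

test_that("freed and fixed trends agree on invariant data and budget overruns warn", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 4, n = 2000), seed = 83)
  mos <- polyMomentsByGroup(d)
  fv <- freedVsFixed(mos, noninvariantParams = list(intercepts = 6L),
                     residualPairs = dmiPair)
  expect_lt(fv$maxAbsDifference, 0.05)
  expect_identical(fv$fixed$variant[1], "fixed-counterfactual")
  expect_warning(freedVsFixed(mos, noninvariantParams = list(intercepts = 1:4),
                              residualPairs = dmiPair), "budget")
})

test_that("one-way ICC handles its degenerate cases and recovers the truth", {
  expect_equal(iccOneway(c(1, 2, 3, 1, 2, 3), c("a", "a", "a", "b", "b", "b")), 0)
  expect_equal(iccOneway(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_error(iccOneway(1:5, rep("a", 5)), "2 clusters")
  set.seed(2)
  cl <- rep(1:200, each = 500)
  x <- rnorm(200, 0, sqrt(0.02))[cl] + rnorm(1e5)
  expect_lt(abs(iccOneway(x, cl) - 0.02), 0.005)
})

test_that("cluster-structured simulation yields a detectable ICC", {
  spec <- popSpec(groups = "g1", n = 20000, nClusters = 100L, clusterSd = 0.3)
  d <- simulateOrdinal(spec, seed = 89)
  expect_false(is.null(d@cluster))
  icc <- iccOneway(responses(d)[, 3], d@cluster)
  expect_gt(icc, 0.01)
  expect_lt(icc, 0.1)
})

test_that("descriptives cover items and the scale mean score", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 2, n = 500), seed = 97)
  tab <- describeItems(d)
  expect_equal(nrow(tab), 2 * 7)
  expect_true(all(c("mean", "sd", "skewness", "kurtosis") %in% names(tab)))
  sc <- tab[tab$item == "scale", ]
  expect_true(all(sc$mean > 1 & sc$mean < 4))
  # right-skewed symptom items
  expect_true(all(tab$skewness[tab$item != "scale"] > 0))
})
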