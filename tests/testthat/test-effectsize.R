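# Expected item scores and the d_MACS effect size against Monte-Carlo
# integration oracles.

refPars <- list(tau = c(-0.674, 0, 0.674), lambda = 0.8, nu = 0, theta = 0.36)

test_that("expected item score respects its limits", {
  expect_equal(expectedItemScore(50, refPars$tau, 0.8, 0, 0.36), 4, tolerance = 1e-9)
  expect_equal(expectedItemScore(-50, refPars$tau, 0.8, 0, 0.36), 1, tolerance = 1e-9)
  # a zero-loading item is flat in the trait
  flat <- expectedItemScore(seq(-3, 3, by = 0.5), refPars$tau, 0, 0, 1)
  expect_equal(diff(range(flat)), 0, tolerance = 1e-12)
  expect_error(expectedItemScore(0, refPars$tau, 0.8, 0, -0.1), "theta")
})

test_that("expected item score matches a simulation at a fixed trait value", {
  eta <- 0.5
  set.seed(101)
  ystar <- refPars$nu + refPars$lambda * eta + rnorm(1e6, 0, sqrt(refPars$theta))
  ysim <- 1 + findInterval(ystar, refPars$tau)
  expect_equal(expectedItemScore(eta, refPars$tau, refPars$lambda,
                                 refPars$nu, refPars$theta),
               mean(ysim), tolerance = 0.003)
})

test_that("d_MACS is zero for identical parameters and matches Monte Carlo", {
  expect_equal(dmacs(refPars, refPars)$d, 0)
  foc <- refPars; foc$nu <- 0.3
  r <- dmacs(refPars, foc)
  set.seed(7)
  eta <- rnorm(1e6)
  dif <- expectedItemScore(eta, foc$tau, foc$lambda, foc$nu, foc$theta) -
    expectedItemScore(eta, refPars$tau, refPars$lambda, refPars$nu, refPars$theta)
  dMc <- sqrt(mean(dif^2)) / r$pooledSd
  expect_equal(r$d, dMc, tolerance = 0.01)
  expect_identical(r$band, "small")     # ~0.29 sits in the 0.20-0.40 band
})

test_that("d_MACS bands follow the documented cutpoints", {
  foc <- refPars; foc$nu <- 0.05
  expect_identical(dmacs(refPars, foc)$band, "negligible")
  foc$nu <- 0.5
  expect_identical(dmacs(refPars, foc)$band, "medium")
  foc$nu <- 1.5
  expect_identical(dmacs(refPars, foc)$band, "large")
})

test_that("d_MACS grows with the size of the intercept shift", {
  ds <- vapply(c(0.1, 0.2, 0.3, 0.5), function(s) {
    foc <- refPars; foc$nu <- s
    dmacs(refPars, foc)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("quadrature is stable under node doubling", {
  foc <- refPars; foc$nu <- 0.25
  d50 <- dmacs(refPars, foc, nodes = 50)$d
  d100 <- dmacs(refPars, foc, nodes = 100)$d
  expect_lt(abs(d50 - d100), 1e-4)
})

test_that("swapping reference and focal groups changes d when the reference distribution differs", {
  foc <- refPars; foc$nu <- 0.4
  a <- dmacs(refPars, foc, latentRef = c(0, 1), latentFocal = c(1, 1))$d
  b <- dmacs(foc, refPars, latentRef = c(1, 1), latentFocal = c(0, 1))$d
  expect_gt(abs(a - b), 1e-4)
})

test_that("the d_MACS table flags the shifted item across groups", {
  spec <- injectNoninvariance(dmiLikeSpec(nGroups = 3, n = 2500), 5L,
                              "intercept", 0.5, "g3")
  d <- simulateOrdinal(spec, seed = 61)
  mos <- polyMomentsByGroup(d)
  # partial scalar fit: latent means separated, item 5's intercepts free
  fit <- suppressWarnings(
    fitCfa(mos, cfaModel(mos, "intercepts", residualPairs = dmiPair,
                         freeItems = list(intercepts = 5L))))
  tab <- dmacsTable(fit)
  expect_equal(nrow(tab), 12L)   # 6 items x 2 non-reference groups
  d53 <- tab$d[tab$item == "item_5" & tab$group == "g3"]
  others <- tab$d[!(tab$item == "item_5" & tab$group == "g3")]
  expect_gt(d53, max(others))
  expect_gt(d53, 0.2)
})
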