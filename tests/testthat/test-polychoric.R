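# Threshold and polychoric estimators against closed forms, inversion of
# exact expected tables, and resampling-based variance oracles.

test_that("thresholds are normal quantiles of cumulative proportions", {
  expect_equal(as.numeric(estimateThresholds(c(25, 25, 25, 25))),
               qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)
  expect_equal(as.numeric(estimateThresholds(c(50, 50))), 0)
  expect_error(estimateThresholds(c(0, 100, 0, 0)), "degenerate")
  expect_warning(tau <- estimateThresholds(c(10, 0, 30, 60)), "collapsed")
  expect_equal(as.numeric(tau), qnorm(c(0.1, 0.4)), tolerance = 1e-12)
  expect_error(estimateThresholds(c(10, 0, 30, 60), strict = TRUE), "strict")
})

test_that("thresholds are recovered from simulated data", {
  spec <- popSpec(groups = "g1", n = 1e5, tau = c(-1, 0, 1))
  d <- simulateOrdinal(spec, seed = 17)
  for (j in 1:6) {
    tau <- estimateThresholds(tabulate(responses(d)[, j], 4))
    expect_true(all(abs(tau - c(-1, 0, 1)) < 0.02))
  }
})

test_that("polychoric estimator inverts exact expected tables", {
  tau <- qnorm(c(0.25, 0.5, 0.75))
  # independence: product of margins
  m <- diff(pnorm(c(-Inf, tau, Inf)))
  tabInd <- outer(m, m) * 1e6
  expect_lt(abs(estimatePolychoric(tabInd, tau, tau)$rho), 1e-3)
  # expected table under rho = 0.5 must be inverted to 0.500
  tab <- ordinvar:::.cellProbs(tau, tau, 0.5) * 1e6
  expect_equal(estimatePolychoric(tab, tau, tau)$rho, 0.5, tolerance = 1e-3)
  # and under asymmetric thresholds and negative correlation
  tau2 <- c(-0.2, 0.9)
  tab2 <- ordinvar:::.cellProbs(tau, tau2, -0.35) * 1e6
  expect_equal(estimatePolychoric(tab2, tau, tau2)$rho, -0.35, tolerance = 1e-3)
})

test_that("perfect association is clipped at the boundary with a warning", {
  tab <- diag(c(250, 250, 250, 250))
  tau <- qnorm(c(0.25, 0.5, 0.75))
  expect_warning(est <- estimatePolychoric(tab, tau, tau), "boundary")
  expect_equal(est$rho, 0.999)
  expect_true(est$boundary)
})

test_that("zero margins are rejected", {
  tab <- matrix(c(10, 0, 5, 0, 0, 0, 3, 0, 8), 3)
  expect_error(estimatePolychoric(tab, c(-1, 1), c(-1, 1)), "zero margin")
})

test_that("category relabeling direction behaves exactly", {
  spec <- popSpec(groups = "g1", n = 4000, lambda = 0.75)
  d <- simulateOrdinal(spec, seed = 21)
  y1 <- responses(d)[, 1]; y2 <- responses(d)[, 2]
  est <- function(a, b) {
    t1 <- as.numeric(estimateThresholds(tabulate(a, 4)))
    t2 <- as.numeric(estimateThresholds(tabulate(b, 4)))
    estimatePolychoric(ordinvar:::.pairTable(a, b, 4L, 4L), t1, t2)$rho
  }
  r <- est(y1, y2)
  expect_equal(est(5L - y1, 5L - y2), r, tolerance = 1e-6)
  expect_equal(est(5L - y1, y2), -r, tolerance = 1e-6)
})

test_that("pairwise sample sizes under MCAR follow the binomial law", {
  n <- 4000
  spec <- dmiLikeSpec(nGroups = 1, n = n, missRate = 0.05)
  d <- simulateOrdinal(spec, seed = 41)
  mo <- polyMoments(d)
  pN <- mo@pairN[upper.tri(mo@pairN)]
  bounds <- qbinom(c(0.005, 0.995), n, 0.95^2)
  expect_true(all(pN >= bounds[1] & pN <= bounds[2]))
  # complete data: all pairwise n equal the group n
  d0 <- simulateOrdinal(dmiLikeSpec(nGroups = 1, n = 500, missRate = 0), seed = 2)
  mo0 <- polyMoments(d0)
  expect_true(all(mo0@pairN == 500))
})

test_that("influence-function variance agrees with a grouped jackknife", {
  n <- 5000
  spec <- popSpec(groups = "g1", n = n, nItems = 2L, lambda = 0.75,
                  tau = c(-0.3, 0.4, 1.1))
  d <- simulateOrdinal(spec, seed = 8)
  mo <- polyMoments(d)
  vIF <- diag(mo@acov)[7] / n      # moment 7 = the correlation (2x3 thresholds first)
  y <- responses(d)
  B <- 200L
  blk <- rep(seq_len(B), length.out = n)
  est <- function(rows) {
    a <- y[rows, 1]; b <- y[rows, 2]
    t1 <- as.numeric(estimateThresholds(tabulate(a, 4)))
    t2 <- as.numeric(estimateThresholds(tabulate(b, 4)))
    estimatePolychoric(ordinvar:::.pairTable(a, b, 4L, 4L), t1, t2)$rho
  }
  loo <- vapply(seq_len(B), function(bb) est(which(blk != bb)), numeric(1))
  vJack <- (B - 1) / B * sum((loo - mean(loo))^2)
  expect_lt(abs(vIF - vJack) / vJack, 0.2)
})

test_that("asymptotic variances scale as 1/n", {
  # the stored covariance is on the sqrt(n) scale, so its diagonal should be
  # stable across a 4-point n grid (equivalently var(rho-hat) halves with 2n)
  spec1 <- popSpec(groups = "g1", n = 2000, nItems = 2L, lambda = 0.7)
  base <- NULL
  for (n in c(2000, 4000, 8000, 16000)) {
    spec <- popSpec(groups = "g1", n = n, nItems = 2L, lambda = 0.7)
    mo <- polyMoments(simulateOrdinal(spec, seed = 14))
    v <- diag(mo@acov)[7]
    if (is.null(base)) base <- v
    expect_equal(v, base, tolerance = 0.15)
  }
})

test_that("group moments validate and export", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 2, n = 800), seed = 6)
  mos <- polyMomentsByGroup(d)
  expect_named(mos, c("g1", "g2"))
  expect_true(validObject(mos$g1))
  p <- tempfile(fileext = ".json")
  momentsToJson(mos$g1, p)
  x <- jsonlite::read_json(p)
  expect_equal(x$n, mos$g1@n)
  expect_length(x$asymptoticVariances, 6 * 3 + 15)
})
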