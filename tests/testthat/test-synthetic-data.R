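# The generator is the testbed for everything downstream: its category
# frequencies must match the normal-ogive closed form, its seeds must be
# reproducible per group, and injections must be local.

test_that("defaults give a fully invariant spec and the grid arithmetic holds", {
  spec <- popSpec(groups = paste0("g", 1:3), n = 100)
  ref <- spec@params[[1]]
  for (g in 2:3) expect_equal(spec@params[[g]], ref)
  grid <- makeGroupGrid(year = 1:10, gender = c("m", "f"), age = 1:5)
  spec2 <- popSpec(groups = grid, n = 1000)
  expect_equal(nrow(spec2@groupInfo), 100L)
  expect_equal(sum(spec2@groupInfo$n), 100000)
})

test_that("invalid generating parameters are rejected by name", {
  expect_error(popSpec(tau = c(0.5, 0.2, 0.8)), "increasing")
  expect_error(popSpec(phi = c(1, -1), groups = c("a", "b")), "phi")
  expect_error(popSpec(residualPairs = rbind(c(1L, 2L)), rho = 1.2), "rho")
  expect_error(popSpec(lambda = 1.2), "residual variance")
  expect_error(popSpec(missRate = 1), "missRate")
})

test_that("category frequencies match the analytic normal-ogive probabilities", {
  n <- 1e5
  tau <- c(-0.674, 0, 0.674)
  spec <- popSpec(groups = "g1", n = n, lambda = 0.8, tau = tau, theta = 0.36)
  d <- simulateOrdinal(spec, seed = 123)
  pTrue <- categoryProbs(tau, lambda = 0.8, theta = 0.36)
  for (j in 1:6) {
    pHat <- tabulate(responses(d)[, j], 4) / n
    mcse <- sqrt(pTrue * (1 - pTrue) / n)
    expect_true(all(abs(pHat - pTrue) < 3.5 * mcse),
                info = sprintf("item %d: max dev %.4f", j, max(abs(pHat - pTrue))))
  }
})

test_that("simulation is seed-deterministic and group streams are independent", {
  spec <- dmiLikeSpec(nGroups = 3, n = 300)
  d1 <- simulateOrdinal(spec, seed = 77)
  d2 <- simulateOrdinal(spec, seed = 77)
  expect_identical(responses(d1), responses(d2))
  expect_false(identical(responses(d1), responses(simulateOrdinal(spec, seed = 78))))
  # adding a group leaves earlier groups' draws untouched
  spec4 <- dmiLikeSpec(nGroups = 4, n = 300)
  d4 <- simulateOrdinal(spec4, seed = 77)
  expect_identical(responses(d1), responses(d4)[1:900, ])
})

test_that("zero loadings leave only residual correlation between items", {
  spec <- popSpec(groups = "g1", n = 50000, lambda = 1e-12,
                  tau = c(-0.674, 0, 0.674), theta = 1,
                  residualPairs = rbind(c(1L, 2L)), rho = 0.3)
  d <- simulateOrdinal(spec, seed = 5)
  mo <- polyMoments(d)
  expect_equal(polychoricCor(mo)[1, 2], 0.3, tolerance = 0.02)
  others <- polychoricCor(mo)[upper.tri(polychoricCor(mo))][-1]
  expect_true(all(abs(others) < 0.02))
})

test_that("missingness is MCAR at the configured rate", {
  spec <- dmiLikeSpec(nGroups = 1, n = 1e5, missRate = 0.05)
  d <- simulateOrdinal(spec, seed = 32)
  y <- responses(d)
  expect_lt(abs(mean(is.na(y)) - 0.05), 0.005)
  # missing indicator of item 1 vs a proxy for the latent trait
  proxy <- rowMeans(y[, -1], na.rm = TRUE)
  r <- cor(is.na(y[, 1]), proxy, use = "complete.obs")
  expect_lt(abs(r), 0.01)
})

test_that("MAR mode ties missingness to the latent trait", {
  spec <- dmiLikeSpec(nGroups = 1, n = 5e4, missRate = 0.05)
  spec@missMode <- "MAR"
  d <- simulateOrdinal(spec, seed = 31)
  y <- responses(d)
  proxy <- rowMeans(y[, -1], na.rm = TRUE)
  r <- cor(is.na(y[, 1]), proxy, use = "complete.obs")
  expect_gt(r, 0.02)
})

test_that("noninvariance injection is local and validated", {
  spec <- dmiLikeSpec(nGroups = 4, n = 100)
  expect_equal(injectNoninvariance(spec, 6L, "intercept", 0, "g3")@params,
               spec@params)
  sh <- injectNoninvariance(spec, 6L, "intercept", 0.3, c("g3", "g4"))
  for (g in c("g1", "g2")) expect_equal(sh@params[[g]], spec@params[[g]])
  expect_equal(sh@params$g3$nu[6], 0.3)
  expect_equal(sh@params$g3$nu[-6], spec@params$g3$nu[-6])
  expect_equal(sh@params$g3$tau, spec@params$g3$tau)
  expect_equal(nrow(sh@injections), 2L)
  expect_error(injectNoninvariance(spec, 2L, "loading", -0.8, "g2"), "lambda <= 0")
  expect_error(injectNoninvariance(spec, 2L, "threshold", c(0, -3, 0), "g2"),
               "non-monotone")
  expect_error(injectNoninvariance(spec, 2L, "intercept", 0.1, "nope"), "unknown")
})

test_that("intercept shift equals an opposite uniform threshold shift", {
  spec <- dmiLikeSpec(nGroups = 2, n = 20000, missRate = 0)
  a <- simulateOrdinal(injectNoninvariance(spec, 3L, "intercept", 0.4, "g2"),
                       seed = 99)
  b <- simulateOrdinal(injectNoninvariance(spec, 3L, "threshold", -0.4, "g2"),
                       seed = 99)
  expect_identical(responses(a), responses(b))
})

test_that("spec serialization round-trips through YAML", {
  spec <- injectNoninvariance(dmiLikeSpec(nGroups = 3, n = 150), 5L,
                              "intercept", 0.2, "g2")
  path <- tempfile(fileext = ".yaml")
  writeSpec(spec, path)
  spec2 <- readSpec(path)
  expect_equal(spec2@params, spec@params, tolerance = 1e-9)
  expect_equal(spec2@groupInfo$n, spec@groupInfo$n)
  expect_identical(responses(simulateOrdinal(spec, 3)),
                   responses(simulateOrdinal(spec2, 3)))
})
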