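# Decision rules, the ladder on invariant and DIF data, partial search
# behavior, and decision auditability.

test_that("delta-fit decision rules apply the published cutoffs", {
  ref <- fakeFit(cfi = 0.995, rmsea = 0.030, df = 50)
  mk <- function(dCfi, dRmsea) fakeFit(0.995 + dCfi, 0.030 + dRmsea, df = 60)
  # identical fits pass trivially
  same <- fakeFit(0.995, 0.030, df = 60)
  cmp <- compareModels(same, ref, "thresholds")
  expect_true(cmp$pass); expect_equal(cmp$deltaCfi, 0); expect_equal(cmp$deltaRmsea, 0)
  # intercept step: strict deltaCFI >= -0.002
  expect_true(compareModels(mk(-0.0019, 0), ref, "intercepts")$pass)
  expect_false(compareModels(mk(-0.0021, 0), ref, "intercepts")$pass)
  # threshold/loading step: joint rule deltaRMSEA <= 0.01 & deltaCFI >= -0.004
  expect_true(compareModels(mk(-0.0035, 0.009), ref, "thresholds")$pass)
  expect_false(compareModels(mk(-0.0045, 0.009), ref, "thresholds")$pass)
  expect_false(compareModels(mk(-0.001, 0.011), ref, "loadings")$pass)
  # an intercept-size violation that the joint rule would tolerate
  expect_true(compareModels(mk(-0.003, 0.002), ref, "loadings")$pass)
  expect_false(compareModels(mk(-0.003, 0.002), ref, "intercepts")$pass)
  # non-nested inputs are rejected
  expect_error(compareModels(ref, same, "thresholds"), "nested")
})

test_that("fewer than two groups is an error", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 1, n = 300), seed = 1)
  expect_error(runLadder(d), "at least 2 groups")
})

test_that("a fully invariant DGP climbs to scalar invariance", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 4, n = 2000), seed = 7)
  lad <- runLadder(d, residualPairs = dmiPair)
  expect_identical(achievedLevel(lad), "scalar")
  tab <- comparisonTable(lad)
  expect_true(all(tab$pass[-1]))
  expect_length(unlist(lad@freed), 0L)
  expect_named(lad@steps, c("configural", "thresholds", "loadings", "intercepts"))
})

test_that("an injected intercept shift is detected and localized", {
  spec <- injectNoninvariance(dmiLikeSpec(nGroups = 4, n = 2000), 6L,
                              "intercept", 0.5, c("g3", "g4"))
  d <- simulateOrdinal(spec, seed = 11)
  lad <- runLadder(d, residualPairs = dmiPair)
  expect_identical(achievedLevel(lad), "partial-scalar")
  expect_equal(lad@freed$intercepts, 6L)
  expect_match(comparisonTable(lad)$model[4], "partial")
})

test_that("partial search reports already-passing steps and budget exhaustion", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 3, n = 1500), seed = 29)
  mos <- polyMomentsByGroup(d)
  conf <- fitCfa(mos, cfaModel(mos, "loadings", residualPairs = dmiPair),
                 checkIdentification = FALSE)
  ps <- partialSearch(mos, conf, "intercepts", residualPairs = dmiPair)
  expect_identical(ps$status, "already-passing")
  expect_length(ps$freed, 0L)
  # four truly shifted items cannot fit within a 3/6 budget; opposite-sign
  # shifts prevent the DIF from being absorbed into the latent means
  spec <- dmiLikeSpec(nGroups = 4, n = 1500)
  for (j in 1:4) spec <- injectNoninvariance(spec, j, "intercept",
                                             c(0.7, 0.7, -0.7, -0.7)[j],
                                             c("g3", "g4"))
  d4 <- simulateOrdinal(spec, seed = 31)
  lad <- runLadder(d4, residualPairs = dmiPair)
  expect_match(achievedLevel(lad), "noninvariant")
  expect_false(grepl("scalar", achievedLevel(lad)))
  expect_error(latentTrend(lad), "not comparable")
})

test_that("releasing a parameter never worsens the minimized fit function", {
  # nesting guarantee: a model with an extra free parameter, warm-started
  # from the restricted solution, can only improve (or tie) the fit function;
  # CFI itself may tick down for an irrelevant release because df drops,
  # which is why the greedy search ranks candidates by decision margin
  spec <- injectNoninvariance(dmiLikeSpec(nGroups = 4, n = 1500), 5L,
                              "intercept", 0.6, c("g3", "g4"))
  d <- simulateOrdinal(spec, seed = 37)
  mos <- polyMomentsByGroup(d)
  strictFit <- fitCfa(mos, cfaModel(mos, "intercepts", residualPairs = dmiPair),
                      checkIdentification = FALSE)
  best <- -Inf
  for (j in 1:6) {
    rel <- fitCfa(mos, cfaModel(mos, "intercepts", residualPairs = dmiPair,
                                freeItems = list(intercepts = j)),
                  warmFrom = strictFit, checkIdentification = FALSE)
    expect_lte(rel@F, strictFit@F + 1e-8)
    if (j == 5) best <- rel@indices["cfi"]
  }
  # the truly shifted item gives the largest CFI improvement
  expect_gte(best, strictFit@indices["cfi"])
})

test_that("recorded decisions replay exactly from the stored deltas", {
  spec <- injectNoninvariance(dmiLikeSpec(nGroups = 4, n = 1200), 2L,
                              "intercept", 0.5, "g4")
  d <- simulateOrdinal(spec, seed = 43)
  lad <- runLadder(d, residualPairs = dmiPair)
  tab <- comparisonTable(lad)
  cfg <- lad@config
  for (i in seq_len(nrow(tab))[-1]) {
    step <- sub("^partial-", "", tab$model[i])
    replay <- if (step == "intercepts")
      tab$deltaCfi[i] >= cfg$deltaCfiMinIntercepts
    else tab$deltaRmsea[i] <= cfg$deltaRmseaMax & tab$deltaCfi[i] >= cfg$deltaCfiMin
    expect_identical(unname(replay), tab$pass[i])
  }
})

test_that("the two-group convenience mode runs an ordinary ladder", {
  d <- simulateOrdinal(dmiLikeSpec(nGroups = 4, n = 900), seed = 53)
  lad <- runTwoGroup(d, "g2", "g4", residualPairs = dmiPair)
  expect_s4_class(lad, "LadderResult")
  expect_identical(groupLabels(lad@steps$configural), c("g2", "g4"))
})
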