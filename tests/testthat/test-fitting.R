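test_that("rSquared matches its definition", {
  expect_identical(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(rSquared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SSres 1, SStot 2
  expect_error(rSquared(c(1, 1), c(1, 2)), "zero variance")
  expect_error(rSquared(1, 1), "equal length")
})

test_that("single fit with a measured floor recovers published generators", {
  cases <- list(
    list(p = tbl$promoterSingle, floor = 16),
    list(p = tbl$promoterSingleAlt, floor = 1.2),
    list(p = tbl$elongationSingle, floor = 37))
  for (cs in cases) {
    cur <- genInductionCurve(cs$p, defaultActivityLevels())
    fit <- fitSingle(cur, yMin = cs$floor)
    est <- fitParams(fit)
    expect_true(converged(fit))
    expect_equal(kappaR(est), kappaR(cs$p), tolerance = 1e-4)
    expect_equal(alphaR(est), alphaR(cs$p), tolerance = 1e-4)
    expect_equal(yMax(est), yMax(cs$p), tolerance = 1e-4)
    expect_identical(yMin(est), cs$floor)
    expect_gt(rSquaredOf(fit), 1 - 1e-9)
  }
})

test_that("without a measured floor the ridge is flagged and kappa survives", {
  # (yMin, alphaR) enter the response only through floor and ceiling: a
  # single curve cannot separate them, but kappaR and yMax are identifiable
  p <- tbl$promoterSingle
  cur <- genInductionCurve(p, defaultActivityLevels())
  fit <- fitSingle(cur)
  expect_setequal(unidentifiable(fit), c("yMin", "alphaR"))
  est <- fitParams(fit)
  expect_equal(kappaR(est), 0.043, tolerance = 1e-4)
  expect_equal(yMax(est), 6800, tolerance = 1e-4)
  # the reported ridge point reproduces the same curve
  expect_equal(responseSingle(xValues(cur), est), yMean(cur),
               tolerance = 1e-6)
  # and the implied floor matches the generator's floor
  floorHat <- (yMax(est) - yMin(est)) / alphaR(est) + yMin(est)
  expect_equal(floorHat, 6784 / 120 + 16, tolerance = 1e-4)
})

test_that("a flat curve flags kappa and alpha as unidentifiable", {
  pFlat <- SteadyStateParams(16, 6800, 0.043, 1)  # neutral binder
  cur <- genInductionCurve(pFlat, defaultActivityLevels())
  fit <- fitSingle(cur, yMin = 16)
  expect_true(all(c("kappaR", "alphaR") %in% unidentifiable(fit)))
  expect_false(converged(fit))
  expect_error(fitSingle(InductionCurve(c(0, 1, 2), c(5, 4, 3))), ">= 4")
})

test_that("noiseless random generators are recovered to 1e-3", {
  set.seed(42)
  x <- defaultActivityLevels()
  for (i in 1:40) {
    p <- randomSSParams()
    cur <- genInductionCurve(p, x)
    est <- fitParams(fitSingle(cur, yMin = yMin(p)))
    expect_equal(kappaR(est), kappaR(p), tolerance = 1e-3)
    expect_equal(alphaR(est), alphaR(p), tolerance = 1e-3)
    expect_equal(yMax(est), yMax(p), tolerance = 1e-3)
  }
})

test_that("noisy recovery is accurate to the median-15% level", {
  # log-scale objective: variance-matched to multiplicative lognormal noise
  p <- tbl$promoterSingle
  x <- defaultActivityLevels()
  errK <- errA <- numeric(50)
  for (i in seq_along(errK)) {
    cur <- genInductionCurve(p, x, noiseModel("lognormal", 1.2, 3L,
                                              seed = 1000L + i))
    est <- fitParams(fitSingle(cur, yMin = 16, scale = "log10"))
    errK[i] <- abs(kappaR(est) - 0.043) / 0.043
    errA[i] <- abs(alphaR(est) - 120) / 120
  }
  expect_lt(median(errK), 0.15)
  expect_lt(median(errA), 0.15)
})

test_that("dual fit recovers kappaD/alphaD with frozen singles untouched", {
  g <- gridActivityLevels()
  cases <- list(
    list(dual = tbl$promoterDual, single = tbl$promoterSingle),
    list(dual = tbl$elongationDual, single = tbl$elongationSingle))
  for (cs in cases) {
    grid <- genResponseGrid(cs$dual, g$xR, g$xD)
    fit <- fitDual(grid, cs$single)
    est <- fitParams(fit)
    expect_equal(kappaD(est), kappaD(cs$dual), tolerance = 1e-4)
    expect_equal(alphaD(est), alphaD(cs$dual), tolerance = 0.005)
    # bit-identical pass-through of the frozen parameters
    expect_identical(yMin(est), yMin(cs$single))
    expect_identical(yMax(est), yMax(cs$single))
    expect_identical(kappaR(est), kappaR(cs$single))
    expect_identical(alphaR(est), alphaR(cs$single))
    # noiseless self-generated data: R^2 = 1
    expect_equal(rSquaredOf(fit), 1, tolerance = 1e-9)
  }
})

test_that("a grid without derepressor induction flags alphaD", {
  p <- tbl$promoterDual
  grid <- genResponseGrid(p, gridActivityLevels()$xR, 0)
  fit <- fitDual(grid, tbl$promoterSingle)
  expect_true("alphaD" %in% unidentifiable(fit))
})

test_that("ratio-of-means estimates propagate replicate uncertainty", {
  e <- alphaFromOnOff(100, 10, 50, 5)
  expect_equal(alphaValue(e), 2)
  expect_equal(alphaSigma(e), 2 * sqrt(0.01 + 0.01))  # 0.28284
  e0 <- alphaFromOnOff(7, 0, 7, 0)
  expect_equal(alphaValue(e0), 1)
  expect_identical(alphaSigma(e0), 0)
  eCv <- alphaFromOnOff(100, 10, 100, 10)
  expect_equal(alphaSigma(eCv), sqrt(2) * 0.1)
  expect_error(alphaFromOnOff(100, 1, 0, 1), "meanOn")
})

test_that("relative expression shares the ratio contract", {
  e <- relativeExpression(200, 0, 100, 0)
  expect_equal(alphaValue(e), 2)
  expect_identical(alphaSigma(e), 0)
  e2 <- relativeExpression(4200, 420, 4200, 420)
  expect_equal(alphaValue(e2), 1)
  expect_equal(alphaSigma(e2), sqrt(2) * 0.1)
  expect_error(relativeExpression(100, 1, 0, 1), "circuitMean")
})
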