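test_that("occupancy reproduces the competitive partition function", {
  # empty-ligand and half-saturation cases
  expect_equal(unlist(occupancy(0, 0, KR = 2, KD = 3)),
               c(fFree = 1, fR = 0, fD = 0))
  expect_equal(unlist(occupancy(0.5, 0, KR = 2, KD = 3)),
               c(fFree = 0.5, fR = 0.5, fD = 0))
  # equal competitive partition: weights (1, 1, 1)
  eq <- occupancy(1, 1, KR = 1, KD = 1)
  expect_equal(unlist(eq), c(fFree = 1, fR = 1, fD = 1) / 3)
  expect_error(occupancy(-1, 0, KR = 1), "sR and sD")
  expect_error(occupancy(1, 0, KR = 0), "KR and KD")
})

test_that("occupancy fractions sum to one and stay in [0,1]", {
  set.seed(11)
  n <- 2000
  sR <- 10^runif(n, -4, 4); sD <- 10^runif(n, -4, 4)
  KR <- 10^runif(n, -3, 3); KD <- 10^runif(n, -3, 3)
  f <- occupancy(sR, sD, KR, KD)
  expect_true(all(abs(rowSums(f) - 1) < 1e-12))
  expect_true(all(as.matrix(f) >= 0 & as.matrix(f) <= 1))
})

test_that("mRNA production rate interpolates between bound and free rates", {
  kin <- KineticParams(betaM = 10, beta = 0.3, deltaM = 0.2, KR = 0.5,
                       KD = 0.7, alphaR = 40, alphaD = 2)
  expect_equal(mrnaProductionRate(0, 0, kin), 10.3)
  # saturation limit, evaluated deep into saturation
  expect_equal(mrnaProductionRate(1e9 / 0.5, 0, kin), 10 / 40 + 0.3,
               tolerance = 1e-7)
  # neutral binders leave production at the maximum
  kin1 <- KineticParams(betaM = 10, beta = 0.3, deltaM = 0.2, KR = 0.5,
                        KD = 0.7, alphaR = 1, alphaD = 1)
  expect_equal(mrnaProductionRate(123, 456, kin1), 10.3)
  # occupancy-weighted form agrees with the ratio form
  f <- occupancy(2, 3, 0.5, 0.7)
  expect_equal(mrnaProductionRate(2, 3, kin),
               10 * (f$fFree + f$fR / 40 + f$fD / 2) + 0.3)
})

test_that("mRNA steady state equals the long-time ODE limit", {
  kin <- KineticParams(betaM = 7, beta = 0.2, deltaM = 0.3, KR = 0.04,
                       KD = 0.06, alphaR = 80, alphaD = 1.5)
  expect_equal(mrnaSteadyState(0, 0, kin), 7.2 / 0.3)
  expect_equal(mrnaSteadyState(1e10, 0, kin), (7 / 80 + 0.2) / 0.3,
               tolerance = 1e-7)
  # independent ODE oracle: raw integration of the mRNA balance
  deriv <- function(t, m, p)
    list(mrnaProductionRate(p$sR, p$sD, kin) - kin@deltaM * m)
  sol <- deSolve::lsoda(y = 0, times = c(0, 40 / kin@deltaM), func = deriv,
                        parms = list(sR = 30, sD = 12),
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(as.numeric(sol[2, 2]), mrnaSteadyState(30, 12, kin),
               tolerance = 1e-6)
})

test_that("single-guide response hits its ceiling, floor and neutral limits", {
  p <- tbl$promoterSingle  # yMin 16, yMax 6800, kappaR 0.043, alphaR 120
  expect_identical(responseSingle(0, p), 6800)
  # saturated floor (yMax - yMin)/alphaR + yMin
  expect_equal(responseSingle(Inf, p), 6784 / 120 + 16)
  expect_equal(responseSingle(1e9 / 0.043, p), 72.5333333, tolerance = 1e-6)
  p1 <- SteadyStateParams(16, 6800, 0.043, 1)
  expect_equal(responseSingle(c(0, 5, 1e6), p1), rep(6800, 3))
  expect_error(responseSingle(-1, p), ">= 0")
})

test_that("dual response reduces to the single response and saturates", {
  p <- tbl$promoterDual
  x <- c(0, 10^seq(0, 4, length.out = 9))
  expect_identical(responseDual(x, 0, p), responseSingle(x, p))
  # alphaD = 1: sgD-saturated locus is fully productive
  expect_equal(responseDual(0, 5000, p), 6800, tolerance = 1e-4)
  expect_equal(responseDual(300, Inf, p), 6800)
  expect_identical(responseDual(0, 0, p), 6800)
  expect_error(responseDual(1, 1, tbl$promoterSingle), "kappaD")
})

test_that("dual response is monotone and bounded", {
  p <- tbl$promoterDual  # alphaR 120 > 1, alphaD = 1
  xs <- 10^seq(-1, 4, length.out = 30)
  for (xd in c(0, 50, 5000)) {
    y <- responseDual(xs, xd, p)
    expect_true(all(diff(y) < 0))  # strictly decreasing in xR
  }
  for (xr in c(10, 500)) {
    y <- responseDual(xr, xs, p)
    expect_true(all(diff(y) > 0))  # strictly increasing in xD
  }
  grid <- expand.grid(xR = c(0, xs), xD = c(0, xs))
  y <- responseDual(grid$xR, grid$xD, p)
  floorY <- (6800 - 16) / max(120, 1) + 16
  expect_true(all(y <= 6800 + 1e-9 & y >= floorY - 1e-9))
})

test_that("deep saturation makes the response a function of the input ratio", {
  p <- tbl$promoterDual
  xr <- 1e3 / kappaR(p)  # kappa_R * x_R = 1e3; r >= 1 keeps kappa_D x_D >= 1e3
  for (r in c(1, 3, 10)) {
    y1 <- responseDual(xr, r * xr, p)
    y2 <- responseDual(1e3 * xr, 1e3 * r * xr, p)
    expect_lt(abs(y2 - y1) / y1, 0.001)
  }
})

test_that("fold change compares two input states", {
  p <- tbl$promoterSingle
  expect_equal(foldChange(p, c(10, 0), c(10, 0)), 1)
  expect_equal(foldChange(p, c(0, 0), c(Inf, 0)), 6800 / (6784 / 120 + 16))
  pNeutral <- SteadyStateParams(16, 6800, 0.043, 1, kappaD = 0.06, alphaD = 1)
  expect_equal(foldChange(pNeutral, c(7, 3), c(900, 2)), 1)
  expect_error(foldChange(pNeutral, c(Inf, 1), c(Inf, Inf)), "indeterminate")
})
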