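test_that("long-time simulation reaches the closed-form steady state", {
  set.seed(31)
  for (i in 1:10) {
    kin <- randomKineticParams()
    dp <- DynamicsParams(kin, kTl = runif(1, 0.5, 5),
                         doublingTime = runif(1, 20, 60))
    xR <- 10^runif(1, 0, 3); xD <- 10^runif(1, 0, 3)
    horizon <- 30 * max(1 / kin@deltaM, 1 / dp@mu)
    sch <- InductionSchedule(0, xR, xD, duration = horizon)
    tr <- simulateCircuit(sch, dp, dt = horizon / 50, init = c(0, 0))
    mStar <- mrnaSteadyState(xR, xD, kin)
    fStar <- dp@kTl * mStar / dp@mu
    expect_equal(tail(mrnaLevels(tr), 1), mStar, tolerance = 1e-6)
    expect_equal(tail(fluorLevels(tr), 1), fStar, tolerance = 1e-6)
  }
})

test_that("a system started at steady state stays flat", {
  kin <- KineticParams(betaM = 10, beta = 0.1, deltaM = 0.2, KR = 0.043,
                       KD = 0.063, alphaR = 120, alphaD = 1)
  dp <- DynamicsParams(kin, kTl = 2, doublingTime = 36)
  sch <- InductionSchedule(0, 0, 0, duration = 300)
  tr <- simulateCircuit(sch, dp, dt = 10)  # default init: phase-1 steady state
  expect_equal(max(abs(mrnaLevels(tr) - mrnaLevels(tr)[1])) /
                 mrnaLevels(tr)[1], 0, tolerance = 1e-8)
  expect_equal(max(abs(fluorLevels(tr) - fluorLevels(tr)[1])) /
                 fluorLevels(tr)[1], 0, tolerance = 1e-8)
})

test_that("complete repression decays the reporter at the dilution rate", {
  # near-total shutoff: the reporter relaxes to its floor as
  # f(t) ~ floor + (f0 - floor) 2^(-t/doublingTime)
  kin <- KineticParams(betaM = 10, beta = 0, deltaM = 0.5, KR = 1,
                       KD = 1, alphaR = 1e6, alphaD = 1)
  dp <- DynamicsParams(kin, kTl = 2, doublingTime = 36)
  sch <- InductionSchedule(0, xR = 1e9, xD = 0, duration = 400)
  m0 <- mrnaSteadyState(0, 0, kin)
  f0 <- dp@kTl * m0 / dp@mu
  tr <- simulateCircuit(sch, dp, dt = 4, init = c(m0, f0))
  mF <- mrnaSteadyState(1e9, 0, kin)
  fF <- dp@kTl * mF / dp@mu
  tt <- timePoints(tr)
  # exact late-time solution: the mRNA transient (rate deltaM) adds to the
  # dilution-mode amplitude, then decays away within minutes
  B <- dp@kTl * (m0 - mF) / (dp@mu - kin@deltaM)
  A <- (f0 - fF) - B
  late <- tt >= 60
  pred <- fF + A * exp(-dp@mu * tt)
  expect_equal(fluorLevels(tr)[late], pred[late], tolerance = 1e-6)
  # halving time of the floor-subtracted reporter equals the doubling time
  fAt <- function(t) approx(tt, fluorLevels(tr) - fF, xout = t)$y
  expect_equal(fAt(200 + 36) / fAt(200), 0.5, tolerance = 1e-3)
  # ~100-fold repression within 6 h when the floor is far below the start
  expect_gt(f0 / (fF + (f0 - fF) * 2^(-360 / 36)), 100)
})

test_that("trajectories stay non-negative and label phases at events", {
  kin <- KineticParams(betaM = 10, beta = 0.1, deltaM = 0.2, KR = 0.043,
                       KD = 0.063, alphaR = 120, alphaD = 1)
  dp <- DynamicsParams(kin, kTl = 2, doublingTime = 36)
  sch <- InductionSchedule(c(0, 360), xR = c(5000, 0), xD = c(0, 5000),
                           duration = 480)
  tr <- simulateCircuit(sch, dp, dt = 30, init = c(0, 0))
  expect_true(all(mrnaLevels(tr) >= 0) && all(fluorLevels(tr) >= 0))
  expect_identical(unique(phaseLabels(tr)[timePoints(tr) < 360]), 1L)
  expect_identical(unique(phaseLabels(tr)[timePoints(tr) > 360]), 2L)
})

test_that("fold derepression reads ratios off the trajectory", {
  flat <- new("Trajectory", time = 0:10 * 1.0, mrna = rep(1, 11),
              fluor = rep(5, 11), phase = rep(1L, 11))
  expect_equal(foldDerepressionAt(flat, 0, 10), 1)
  # pure exponential recovery with known rate
  tt <- seq(0, 100, by = 1)
  expo <- new("Trajectory", time = tt, mrna = rep(1, length(tt)),
              fluor = 2 * exp(0.03 * tt), phase = rep(1L, length(tt)))
  expect_equal(foldDerepressionAt(expo, 10, 60), exp(0.03 * 50),
               tolerance = 1e-3)
  expect_error(foldDerepressionAt(flat, 6, 2), "precede")
  expect_error(foldDerepressionAt(flat, 0, 99), "within")
})

test_that("dynamics parameters enforce the growth-rate link", {
  kin <- KineticParams(betaM = 1, beta = 0, deltaM = 0.1, KR = 1, KD = 1,
                       alphaR = 10, alphaD = 1)
  dp <- DynamicsParams(kin, doublingTime = 36)
  expect_equal(dp@mu, log(2) / 36)
  expect_error(new("DynamicsParams", kin = kin, kTl = 1, mu = 0.5,
                   doublingTime = 36), "ln\\(2\\)")
})
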