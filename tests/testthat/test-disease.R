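# Ferritin turnover model: status scaling, conversion rate, steady states,
# trajectory simulation and its oracles.

test_that("disease-status scaling is the stated power law", {
  dis <- diseaseParameters()
  atMed <- diseaseStatusScaling(2260, dis)
  expect_equal(atMed$scl, dis@sclRef)
  expect_equal(atMed$shp, dis@shpRef)
  # doubling ferritin multiplies the scale by 2^0.845 = 1.79626
  twice <- diseaseStatusScaling(2 * 2260, dis)
  expect_equal(twice$scl / dis@sclRef, 1.79626, tolerance = 1e-5)
  expect_equal(twice$shp / dis@shpRef, 2^1.29, tolerance = 1e-12)
  # zero exponents give the identity at any ferritin
  dis0 <- diseaseParameters(thetaScl = 0, thetaShp = 0)
  sc <- diseaseStatusScaling(c(100, 5000, 9000), dis0)
  expect_true(all(sc$scl == dis0@sclRef))
  expect_true(all(sc$shp == dis0@shpRef))
  expect_error(diseaseStatusScaling(-1, dis), ">= 0")
})

test_that("conversion rate at the published parameters", {
  dis <- diseaseParameters()
  # 0.383 * exp(-0.00026 * 2260) = 0.21282 (scaling factor is 1 at median)
  expect_equal(conversionRate(2260, dis), 0.21282, tolerance = 1e-4)
  # flat when the shape is zero and exponents are zero
  disFlat <- diseaseParameters(shpRef = 0, thetaScl = 0, thetaShp = 0)
  expect_equal(conversionRate(c(10, 1000, 1e5), disFlat),
               rep(disFlat@sclRef, 3))
  # vanishes at extreme overload (exponential beats the power law)
  expect_lt(conversionRate(2e5, dis), 1e-12)
})

test_that("drug effect is linear in exposure", {
  drg <- drugEffectParameters()
  expect_equal(drugEffect(0, drg), 0)
  expect_equal(drugEffect(1, drg), 4.81)
  expect_equal(drugEffect(2 * 1.7, drg), 2 * drugEffect(1.7, drg))
  expect_error(drugEffect(-1, drg), ">= 0")
})

test_that("turnover right-hand side has the expected signs and fixed points", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  # without transfusions and drug, kin/kout is the fixed point
  disLin <- diseaseParameters(sclRef = 0)
  expect_equal(ferritinRhs(disLin@kin / disLin@kout, 0, disLin, drg), 0)
  # published parameters, no drug: net accumulation at 2500 ug/L
  expect_gt(ferritinRhs(2500, 0, dis, drg), 0)
})

test_that("steady state: exact limits and the untreated level", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  disLin <- diseaseParameters(sclRef = 0)
  expect_equal(steadyStateFerritin(disLin, drg, 0), 2e-4 / 4.5e-6,
               tolerance = 1e-8)
  # with status scaling frozen at the median the untreated steady state is
  # about 8.8e3 ug/L; must agree with the long-run ODE limit within 0.1%
  ssMed <- steadyStateFerritin(dis, drg, 0, statusFerritin = 2260)
  expect_gt(ssMed, 8600); expect_lt(ssMed, 8900)
  tr <- simulateFerritin(3000, c(0, 60 * 8760), 0, dis, drg,
                         statusFerritin = 2260)
  expect_equal(tr$ferritin_ug_per_L[2], ssMed, tolerance = 1e-3)
  # state-dependent default: same consistency (value near 4.9e3)
  ss <- steadyStateFerritin(dis, drg, 0)
  tr2 <- simulateFerritin(3000, c(0, 60 * 8760), 0, dis, drg)
  expect_equal(tr2$ferritin_ug_per_L[2], ss, tolerance = 1e-3)
  # residual actually solved
  expect_lt(abs(ferritinRhs(ss, 0, dis, drg)), 1e-10)
})

test_that("steady state decreases strictly with exposure", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  ss <- sapply(seq(0, 5, by = 0.5), function(e)
    steadyStateFerritin(dis, drg, e))
  expect_true(all(diff(ss) < 0))
})

test_that("trajectory matches the closed-form solution in the linear limit", {
  disLin <- diseaseParameters(sclRef = 0)
  drg <- drugEffectParameters()
  times <- seq(0, 5 * 8760, length.out = 120)
  exact <- linearDecayOracle(1000, times, 0, disLin, drg)
  for (eng in c("bdf", "rk45")) {
    tr <- simulateFerritin(1000, times, 0, disLin, drg, engine = eng)
    expect_lt(max(abs(tr$ferritin_ug_per_L - exact) / exact), 1e-6)
  }
  # with drug on
  exact2 <- linearDecayOracle(1000, times, 2, disLin, drg)
  tr2 <- simulateFerritin(1000, times, 2, disLin, drg, engine = "rk45")
  expect_lt(max(abs(tr2$ferritin_ug_per_L - exact2) / exact2), 1e-6)
})

test_that("both integration engines agree on the full nonlinear model", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  tl <- exposureTimeline(levels = c(4, 0, 2.5), breaks = c(0, 5000, 20000))
  times <- seq(0, 4 * 8760, by = 24 * 20)
  a <- simulateFerritin(6000, times, tl, dis, drg,
                        engine = "rk45")$ferritin_ug_per_L
  b <- simulateFerritin(6000, times, tl, dis, drg,
                        engine = "bdf")$ferritin_ug_per_L
  expect_lt(max(abs(a - b) / pmax(b, 1)), 1e-5)
})

test_that("refining the output grid does not move shared points", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  coarse <- seq(0, 8760, by = 48)
  fine <- seq(0, 8760, by = 24)
  a <- simulateFerritin(5000, coarse, 3, dis, drg,
                        engine = "rk45")$ferritin_ug_per_L
  b <- simulateFerritin(5000, fine, 3, dis, drg,
                        engine = "rk45")$ferritin_ug_per_L
  shared <- match(coarse, fine)
  expect_lt(max(abs(a - b[shared]) / pmax(a, 1)), 1e-6)
})

test_that("trajectories stay strictly positive", {
  drg <- drugEffectParameters(slope = 10)
  set.seed(42)
  for (i in 1:10) {
    dis <- diseaseParameters(kin = runif(1, 0, 1e-3),
                             kout = runif(1, 1e-6, 1e-4),
                             sclRef = runif(1, 0, 1),
                             shpRef = runif(1, 0, 5e-4))
    f0 <- runif(1, 10, 10000)
    tr <- simulateFerritin(f0, seq(0, 2 * 8760, by = 240),
                           runif(1, 0, 8), dis, drg, engine = "rk45")
    expect_true(all(tr$ferritin_ug_per_L > 0))
  }
})

test_that("pointwise larger exposure gives pointwise lower ferritin", {
  dis <- diseaseParameters(); drg <- drugEffectParameters()
  times <- seq(0, 3 * 8760, by = 24 * 10)
  set.seed(7)
  for (i in 1:6) {
    brk <- c(0, sort(runif(3, 0, max(times))))
    lo <- runif(4, 0, 3)
    hi <- lo + runif(4, 0, 3)
    f1 <- simulateFerritin(4000, times, exposureTimeline(lo, brk), dis, drg,
                           engine = "rk45")$ferritin_ug_per_L
    f2 <- simulateFerritin(4000, times, exposureTimeline(hi, brk), dis, drg,
                           engine = "rk45")$ferritin_ug_per_L
    expect_true(all(f2 <= f1 + 1e-6))
  }
})

test_that("simulation input validation", {
  expect_error(simulateFerritin(-1, c(0, 10)), "positive")
  expect_error(simulateFerritin(100, numeric(0)), "empty")
  expect_error(simulateFerritin(100, c(5, 2)), "increasing")
  expect_error(exposureTimeline(c(1, 2), c(0, -5)), "increasing")
  expect_error(exposureTimeline(-1, 0), ">= 0")
})
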