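test_that("gSingle matches the closed form's limits and the integral oracle", {
  # acute limit is exact
  expect_identical(gSingle(0, 91), 1)
  expect_identical(gSingle(0, 1238), 1)

  # frozen values computed with the numerical double-integral oracle
  expect_equal(gSingle(10, 91), 0.9643545649, tolerance = 1e-8)
  expect_equal(gSingle(10, 1238), 0.9973129136, tolerance = 1e-8)
  expect_equal(gSingle(1e4, 91), 0.0180343800, tolerance = 1e-8)

  # long-duration asymptote G -> 2 t0 / theta
  expect_equal(gSingle(1e4, 91), 2 * 91 / 1e4, tolerance = 1e-2)

  # runtime cross-check against the oracle at a few fresh points
  for (theta in c(0.5, 7, 120)) {
    for (t0 in c(91, 1238)) {
      expect_equal(gSingle(theta, t0), gLeaCatchesideNumeric(theta, t0),
                   tolerance = 1e-8)
    }
  }
})

test_that("gSingle is monotone non-increasing in theta and stays in (0, 1]", {
  thetas <- c(0, 10^seq(-3, 5, length.out = 60))
  for (t0 in c(91, 1238)) {
    g <- gSingle(thetas, t0)
    expect_true(all(g > 0 & g <= 1))
    expect_true(all(diff(g) <= 1e-12))
  }
  expect_error(gSingle(10, 0), "t0")
  expect_error(gSingle(-1, 91), "theta")
})

test_that("gDual is the stated convex combination and hits the acute limit", {
  k <- RepairKinetics()   # t0f = 91, t0s = 1238, fast fractions 0.77 / 0.2
  expect_identical(gDual(0, k, "high"), 1)
  expect_identical(gDual(0, k, "low"), 1)

  gf <- gSingle(10, 91)
  gs <- gSingle(10, 1238)
  expect_equal(gDual(10, k, "high"), 0.2 * gf + 0.8 * gs, tolerance = 1e-14)
  expect_equal(gDual(10, k, "low"), 0.77 * gf + 0.23 * gs, tolerance = 1e-14)
  # frozen magnitudes for the 10-min protocol (weighted sums of the
  # oracle-checked single-time factors)
  expect_equal(gDual(10, k, "high"), 0.9907212439, tolerance = 1e-8)
  expect_equal(gDual(10, k, "low"), 0.9719349851, tolerance = 1e-8)

  # protocol objects and raw durations agree
  expect_identical(gDual(IrradiationProtocol(10), k, "high"),
                   gDual(10, k, "high"))
  expect_error(gDual(10, k, fracFastOverride = 1.2), "fracFastOverride")
})

test_that("reference survival evaluates the MLQ exponent", {
  co <- co60Params()
  expect_identical(survivalReference(0, co), 1)
  expect_equal(survivalReference(5, co), exp(-1.55), tolerance = 1e-12)
  expect_equal(survivalReference(5, xrayParams()), exp(-3.05),
               tolerance = 1e-12)
  # strictly decreasing
  d <- seq(0, 12, by = 0.5)
  expect_true(all(diff(survivalReference(d, co)) < 0))
  expect_error(survivalReference(-1, co), "dose")
  expect_error(survivalReference(5, co, gFactor = 0), "gFactor")
})

test_that("mixed-field survival reduces exactly to single components", {
  ps <- gbmParameters()
  g <- mixedFieldGFactors(10, kinetics(ps))

  expect_identical(survivalMixedField(MixedFieldDose(0, 0, 0), ps, 10), 1)

  # photon-only reduces to the reference curve with the photon G
  for (D in c(1, 3, 7)) {
    expect_equal(
      survivalMixedField(MixedFieldDose(photon = D), ps, 10),
      survivalReference(D, componentParameters(ps, "photon"), g$gGamma),
      tolerance = 1e-15)
    expect_equal(
      survivalMixedField(MixedFieldDose(neutron = D), ps, 10),
      survivalReference(D, componentParameters(ps, "neutron"), g$gN),
      tolerance = 1e-15)
    expect_equal(
      survivalMixedField(MixedFieldDose(boron = D), ps, 10),
      survivalReference(D, componentParameters(ps, "boron"), g$gB),
      tolerance = 1e-15)
  }
})

test_that("log-survival is additive up to the synergy term", {
  ps <- gbmParameters()
  g <- mixedFieldGFactors(10, kinetics(ps))
  dB <- 2; dN <- 1.5; dG <- 0.8
  sAll <- survivalMixedField(MixedFieldDose(dB, dN, dG), ps, 10)
  sProd <- survivalMixedField(MixedFieldDose(boron = dB), ps, 10) *
    survivalMixedField(MixedFieldDose(neutron = dN), ps, 10) *
    survivalMixedField(MixedFieldDose(photon = dG), ps, 10)
  bB <- beta(componentParameters(ps, "boron"))
  bN <- beta(componentParameters(ps, "neutron"))
  bG <- beta(componentParameters(ps, "photon"))
  mq <- 2 * g$gBN * sqrt(bB * bN) * dB * dN +
    2 * g$gBGamma * sqrt(bB * bG) * dB * dG +
    2 * g$gGammaN * sqrt(bG * bN) * dG * dN
  expect_equal(log(sAll), log(sProd) - mq, tolerance = 1e-12)

  # acute, unit G: frozen independent term-by-term summation
  sAcute <- survivalMixedField(MixedFieldDose(1, 1, 1), ps, 0)
  expect_equal(sAcute, 0.0119144896728, tolerance = 1e-10)
})

test_that("foci intensity is a normalized decreasing bi-exponential", {
  expect_identical(fociIntensity(0, 0.77, 91, 1238), 1)
  expect_equal(fociIntensity(91, 0.77, 91, 1238), 0.4969672749,
               tolerance = 1e-9)
  tt <- seq(0, 5000, by = 100)
  ii <- fociIntensity(tt, 0.77, 91, 1238)
  expect_true(all(diff(ii) < 0))
  expect_true(all(ii > 0))
  expect_lt(fociIntensity(1e6, 0.77, 91, 1238), 1e-10)
  expect_error(fociIntensity(10, 0.77, -1, 1238), "repair times")
  expect_error(fociIntensity(-5, 0.77, 91, 1238), "t")
})

test_that("value classes enforce their invariants", {
  expect_error(RepairKinetics(t0Fast = 2000, t0Slow = 100), "t0Fast")
  expect_error(RepairKinetics(fracFastLowLET = 1.5), "fracFastLowLET")
  expect_error(LQParameters(-0.1, 0.02), "alpha")
  expect_error(MixedFieldDose(boron = -1), "dose components")
  expect_error(IrradiationProtocol(-5), "duration")
  # parameter sets check LET classes
  expect_error(RadiobiologicalParameterSet(
    photon = LQParameters(0.21, 0.02, "high"),
    neutron = neutronCo60Params(), boron = boronParams(),
    kinetics = RepairKinetics(), label = "x"), "low LET")
})
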