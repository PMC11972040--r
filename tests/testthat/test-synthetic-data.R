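test_that("generators are pure functions of inputs and seed", {
  truth <- gbmParameters()
  des <- standardAssayDesign("bpa_bnct")
  a1 <- generateClonogenicAssay(truth, des, seed = 7)
  a2 <- generateClonogenicAssay(truth, des, seed = 7)
  a3 <- generateClonogenicAssay(truth, des, seed = 8)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))

  f1 <- generateFociSeries(seed = 3)
  f2 <- generateFociSeries(seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, generateFociSeries(seed = 4)))

  p1 <- generatePhantomField(PhantomSpec(), seed = 2)
  p2 <- generatePhantomField(PhantomSpec(), seed = 2)
  expect_identical(p1$field@photon, p2$field@photon)
  expect_false(identical(p1$field@photon,
                         generatePhantomField(PhantomSpec(), seed = 9)$field@photon))

  # generators do not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generateClonogenicAssay(truth, des, seed = 7))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("zero-dose control survives at ~1 within Poisson error", {
  truth <- gbmParameters()
  des <- AssayDesign(condition = "reference_photon",
                     doses = data.frame(boron = 0, neutron = 0, photon = 0),
                     durationMin = 0, cellsSeeded = 2000,
                     platingEfficiency = 0.7, replicates = 3L,
                     boronSigmaRel = 0)
  a <- generateClonogenicAssay(truth, des, seed = 1)
  expect_lt(abs(a$surviving_fraction - 1), 3 * a$sf_sigma + 1e-12)
})

test_that("empirical survival converges to model survival at large n", {
  truth <- gbmParameters()
  des <- AssayDesign(condition = "bpa_bnct",
                     doses = data.frame(boron = 2, neutron = 1, photon = 0.5),
                     durationMin = 10, cellsSeeded = 1e6,
                     platingEfficiency = 0.7, replicates = 1L,
                     boronSigmaRel = 0)
  a <- generateClonogenicAssay(truth, des, seed = 21)
  sModel <- survivalMixedField(MixedFieldDose(2, 1, 0.5), truth, 10)
  expect_lt(abs(a$surviving_fraction - sModel), 3 * a$sf_sigma)
})

test_that("empirical survival is an unbiased estimator of model survival", {
  truth <- gbmParameters()
  des <- AssayDesign(condition = "beam_only",
                     doses = data.frame(boron = 0, neutron = 2, photon = 0.2),
                     durationMin = 10, cellsSeeded = 1000,
                     platingEfficiency = 0.7, replicates = 3L,
                     boronSigmaRel = 0)
  sModel <- survivalMixedField(MixedFieldDose(0, 2, 0.2), truth, 10)
  nrep <- 1000
  sf <- vapply(seq_len(nrep), function(r)
    generateClonogenicAssay(truth, des, seed = 5000 + r)$surviving_fraction,
    numeric(1))
  se <- stats::sd(sf) / sqrt(nrep)
  expect_lt(abs(mean(sf) - sModel), 3 * se)
})

test_that("boron-dose perturbation only affects the reported boron dose", {
  truth <- gbmParameters()
  des <- standardAssayDesign("bpa_bnct", boronSigmaRel = 0.05)
  a <- generateClonogenicAssay(truth, des, seed = 3)
  expect_false(all(a$d_boron == des@doses$boron))  # perturbed (measured)
  expect_identical(a$d_neutron, des@doses$neutron)
  expect_equal(a$d_boron_sigma, 0.05 * a$d_boron, tolerance = 1e-12)
})

test_that("foci series generator reproduces the model exactly without noise", {
  k <- RepairKinetics()
  tt <- seq(0, 1440, by = 120)
  s <- generateFociSeries(k, tt, noiseSigma = 0, seed = 1)
  expect_equal(s$intensity, fociIntensity(tt, 0.77, 91, 1238),
               tolerance = 1e-12)
  expect_equal(s$intensity[1], 1)
  expect_error(generateFociSeries(k, numeric(0)), "invalid design")
  expect_error(generateFociSeries(k, c(10, 5)), "strictly increasing")
})

test_that("phantom fields decay along the beam axis from the surface rates", {
  spec <- PhantomSpec()
  ph <- generatePhantomField(spec, seed = 1, noiseRel = 0)
  g <- ph$field@photon
  # surface slice equals the attenuated surface rate at half-voxel depth
  depth0 <- (0.5 * spec@spacing[3]) / 10
  expect_equal(unname(g[1, 1, 1]),
               spec@surfaceDoseRates[["photon"]] *
                 exp(-depth0 / spec@attenuationLengths[["photon"]]),
               tolerance = 1e-12)
  # monotone decay along the beam axis
  prof <- g[1, 1, ]
  expect_true(all(diff(prof) < 0))
  # tumor and brain masks partition the grid
  expect_true(all(xor(ph$rois$tumor@mask, ph$rois$brain@mask)))
  expect_equal(ph$rois$tumor@boronConcentration, 40)
  expect_equal(ph$rois$brain@boronConcentration, 13.6)

  expect_error(PhantomSpec(shape = c(4L, 4L, 4L), spacing = c(5, 5, 5),
                           tumorCenter = c(2, 2, 2), tumorRadius = 50),
               "outside")
})

test_that("noise-free uniform phantom round-trips through the scalar model", {
  # near-infinite attenuation lengths make the field uniform
  spec <- PhantomSpec(attenuationLengths = c(boronPerPpm = 1e9,
                                             thermalNeutron = 1e9,
                                             fastNeutron = 1e9, photon = 1e9))
  ph <- generatePhantomField(spec, seed = 1, noiseRel = 0)
  t <- 30
  eq <- convertField(ph$field, ph$rois$tumor, "isoeffective",
                     params = gbmParameters(), irradiationTime = t)
  sr <- spec@surfaceDoseRates
  dScalar <- isoeffectiveDose(
    MixedFieldDose(sr[["boronPerPpm"]] * 40 * t,
                   (sr[["thermalNeutron"]] + sr[["fastNeutron"]]) * t,
                   sr[["photon"]] * t),
    gbmParameters(), protocol = t)
  s <- doseStatistics(eq, ph$rois$tumor)
  expect_equal(s@dMax, dScalar, tolerance = 1e-6)
  expect_equal(s@dMin, dScalar, tolerance = 1e-6)
})
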