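uniformField <- function(dB = 0, dN = 0, dG = 0, dim3 = c(4, 4, 4),
                         mode = "absolute") {
  mk <- function(v) array(v, dim3)
  DoseComponentField(boronPerPpm = mk(dB), thermalNeutron = mk(dN / 2),
                     fastNeutron = mk(dN / 2), photon = mk(dG),
                     spacing = c(5, 5, 5), origin = c(0, 0, 0),
                     unitsMode = mode)
}

wholeMask <- function(dim3 = c(4, 4, 4), ppm = 1) {
  ROIMask(mask = array(TRUE, dim3), name = "ROI", boronConcentration = ppm)
}

test_that("uniform-field conversion equals the scalar model everywhere", {
  ps <- gbmParameters()
  # boron grid is per-ppm: 10 Gy per ppm at 1 ppm gives D_B = 10 Gy
  f <- uniformField(dB = 10)
  eq <- convertField(f, wholeMask(), "isoeffective", params = ps)
  expect_equal(unname(eq[1, 1, 1]), 33.8340440589, tolerance = 1e-9)
  expect_equal(max(eq) - min(eq), 0)

  # unit weights give the physical total dose voxelwise
  f2 <- uniformField(dB = 2, dN = 3, dG = 4)
  eqW <- convertField(f2, wholeMask(), "rbe_weighted",
                      weights = RBEWeights(1, 1, 1, "physical"))
  expect_equal(unname(eqW[2, 3, 1]), 9, tolerance = 1e-12)

  # zero field converts to zero
  eq0 <- convertField(uniformField(), wholeMask(), "rbe_weighted",
                      weights = RBEWeights())
  expect_true(all(eq0 == 0))

  # shape mismatch is a registration error
  expect_error(convertField(f, wholeMask(c(3, 4, 4)), "isoeffective",
                            params = ps), "registration")
})

test_that("boron scaling by ROI concentration and time scaling apply in rate mode", {
  ps <- gbmParameters()
  # per-ppm boron rate 0.01 Gy/min/ppm, 40 ppm, 25 min -> D_B = 10 Gy
  f <- uniformField(dB = 0.01, mode = "rate")
  roi <- wholeMask(ppm = 40)
  eq <- convertField(f, roi, "isoeffective", params = ps,
                     irradiationTime = 25)
  # theta = 25 min protracts the mixed field slightly
  dExp <- isoeffectiveDose(MixedFieldDose(boron = 10), ps, protocol = 25)
  expect_equal(unname(eq[1, 1, 1]), dExp, tolerance = 1e-12)
  expect_error(convertField(f, roi, "isoeffective", params = ps),
               "irradiationTime")
})

test_that("DVH is a mass-balanced non-increasing curve", {
  # two-voxel enumerable case
  g <- array(NA_real_, c(2, 1, 1)); g[] <- c(2, 4)
  roi <- ROIMask(mask = array(TRUE, c(2, 1, 1)), name = "two",
                 boronConcentration = 0)
  dvh <- computeDVH(g, roi, nBins = 64L)
  expect_equal(dvh@volumeFraction[1], 1)
  expect_equal(dvh@volumeFraction[length(dvh@volumeFraction)], 0)
  at3 <- approx(dvh@doseEdges, dvh@volumeFraction, xout = 3,
                method = "constant")$y
  expect_equal(at3, 0.5)

  # uniform grid: step function dropping at the dose
  gu <- array(5, c(3, 3, 3))
  dvhU <- computeDVH(gu, wholeMask(c(3, 3, 3)), nBins = 32L)
  expect_true(all(dvhU@volumeFraction[-length(dvhU@volumeFraction)] == 1))

  # seeded phantom: every edge equals the brute-force voxel-count ratio
  ph <- generatePhantomField(PhantomSpec(), seed = 3)
  eq <- convertField(ph$field, ph$rois$tumor, "rbe_weighted",
                     weights = RBEWeights(), irradiationTime = 30)
  dvhT <- computeDVH(eq, ph$rois$tumor, nBins = 100L)
  vals <- eq[ph$rois$tumor@mask]
  for (k in seq(1, 101, by = 10)) {
    expect_equal(dvhT@volumeFraction[k],
                 sum(vals >= dvhT@doseEdges[k]) / length(vals))
  }
  expect_true(all(diff(dvhT@volumeFraction) <= 0))
})

test_that("dose statistics match an exhaustive scan", {
  g <- array(NA_real_, c(2, 1, 1)); g[] <- c(2, 4)
  roi <- ROIMask(mask = array(TRUE, c(2, 1, 1)), name = "two",
                 boronConcentration = 0)
  s <- doseStatistics(g, roi)
  expect_equal(c(s@dMax, s@dMean, s@dMin), c(4, 3, 2))

  withr::with_seed(9, {
    gr <- array(runif(4 * 5 * 6), c(4, 5, 6))
  })
  mask <- gr > 0.3
  if (!any(mask)) mask[1] <- TRUE
  roi2 <- ROIMask(mask = mask, name = "r", boronConcentration = 0)
  s2 <- doseStatistics(gr, roi2)
  expect_equal(s2@dMax, max(gr[mask]))
  expect_equal(s2@dMean, mean(gr[mask]))
  expect_equal(s2@dMin, min(gr[mask]))

  # an ROI with no usable dose values is rejected
  gNA <- array(NA_real_, c(2, 1, 1))
  expect_error(doseStatistics(gNA, roi), "invalid mask")
})

test_that("prescription time scaling is the closed-form linear solution", {
  # uniform weighted rate 0.075 Gy(RBE)/min -> 2.5 Gy(RBE) in 33.3 min
  # (components: 0.01 per-ppm boron at 1 ppm * 3.8 + 0.01 n * 3.2 + 0.005 g)
  f <- uniformField(dB = 0.01, dN = 0.01, dG = 0.005, mode = "rate")
  roi <- wholeMask(ppm = 1)
  w <- RBEWeights()   # 3.8 / 3.2 / 1
  rate <- 0.01 * 3.8 + 0.01 * 3.2 + 0.005
  expect_equal(rate, 0.075)
  t1 <- scaleTimeToPrescription(f, roi, w, limit = 2.5, volumeFraction = 0.5)
  expect_equal(t1, 2.5 / 0.075, tolerance = 1e-12)
  expect_equal(t1, 33.33, tolerance = 1e-3)

  # doubling the rates halves the time
  f2 <- uniformField(dB = 0.02, dN = 0.02, dG = 0.01, mode = "rate")
  expect_equal(scaleTimeToPrescription(f2, roi, w), t1 / 2,
               tolerance = 1e-12)
  # a zero limit needs zero time
  expect_equal(scaleTimeToPrescription(f, roi, w, limit = 0), 0)
  # the prescription is respected on the resulting DVH
  ph <- generatePhantomField(PhantomSpec(), seed = 5)
  tP <- scaleTimeToPrescription(ph$field, ph$rois$brain, w)
  eq <- convertField(ph$field, ph$rois$brain, "rbe_weighted", weights = w,
                     irradiationTime = tP)
  # fine binning: the brain dose range spans the hot entrance region, so
  # the D50 read-off error is about half a bin width
  dvh <- computeDVH(eq, ph$rois$brain, nBins = 4096L)
  expect_equal(dvhDoseAt(dvh, 0.5), 2.5, tolerance = 0.02)
  expect_error(scaleTimeToPrescription(uniformField(mode = "rate"),
                                       roi, w), "unbounded")
})

test_that("percentage differences follow the reference-denominator convention", {
  expect_equal(percentDifference(35.2, 25.5), 28)
  expect_equal(percentDifference(63.4, 34.6), 45)
  expect_equal(percentDifference(76.2, 41.1), 46)
  expect_equal(percentDifference(7, 7), 0)
  expect_equal(percentDifference(35.2, 25.5, rounded = FALSE),
               100 * (35.2 - 25.5) / 35.2)
  expect_error(percentDifference(0, 5), "undefined")
})

test_that("RBE-weighted tumor doses exceed isoeffective ones on the phantom", {
  ph <- generatePhantomField(PhantomSpec(), seed = 1)
  w <- RBEWeights()
  ps <- gbmParameters()
  tP <- scaleTimeToPrescription(ph$field, ph$rois$brain, w)
  iso <- convertField(ph$field, ph$rois$tumor, "isoeffective", params = ps,
                      irradiationTime = tP)
  rbe <- convertField(ph$field, ph$rois$tumor, "rbe_weighted", weights = w,
                      irradiationTime = tP)
  sIso <- doseStatistics(iso, ph$rois$tumor, "isoeffective", "GBM")
  sRbe <- doseStatistics(rbe, ph$rois$tumor, "rbe_weighted", "clinic")
  expect_gt(sRbe@dMean, sIso@dMean)
})
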