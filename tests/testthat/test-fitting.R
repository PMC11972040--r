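test_that("repair-kinetics fit recovers noiseless bi-exponential truth", {
  times <- c(0, 30, 60, 120, 240, 360, 480, 720, 960, 1200, 1440, 2880)
  s <- generateFociSeries(RepairKinetics(), times, noiseSigma = 0, seed = 1)
  fit <- fitRepairKinetics(s)
  est <- estimates(fit)
  expect_equal(est[["c"]], 0.77, tolerance = 1e-6)
  expect_equal(est[["t0f"]], 91, tolerance = 1e-6)
  expect_equal(est[["t0s"]], 1238, tolerance = 1e-6)
  expect_true(est[["t0f"]] <= est[["t0s"]])
  expect_lt(fit@details$mse, 1e-12)
})

test_that("single-exponential series is flagged as the nested-model limit", {
  k1 <- RepairKinetics(t0Fast = 300, t0Slow = 300, fracFastLowLET = 1)
  s <- generateFociSeries(k1, seq(0, 1440, by = 120), noiseSigma = 0, seed = 1)
  fit <- fitRepairKinetics(s)
  est <- estimates(fit)
  # either c ~ 1 (slow term vanishes) or the two times coincide
  degenerate <- abs(est[["c"]] - 1) < 1e-3 || abs(est[["c"]]) < 1e-3 ||
    abs(est[["t0f"]] - est[["t0s"]]) / est[["t0s"]] < 1e-3 ||
    any(boundaryFlags(fit))
  expect_true(degenerate)
  # the fit still reproduces the curve
  pred <- fociIntensity(s$time, est[["c"]], est[["t0f"]], est[["t0s"]])
  expect_equal(pred, s$intensity, tolerance = 1e-5)
})

test_that("repair-kinetics estimates are unbiased under noise", {
  times <- seq(0, 1440, by = 96)
  nrep <- 200
  est <- matrix(NA_real_, nrep, 3)
  for (r in seq_len(nrep)) {
    s <- generateFociSeries(RepairKinetics(), times, noiseSigma = 0.05,
                            seed = 4000 + r)
    est[r, ] <- estimates(fitRepairKinetics(s))
  }
  truth <- c(0.77, 91, 1238)
  for (j in 1:3) {
    se <- stats::sd(est[, j]) / sqrt(nrep)
    # slow-time estimates are heavy-tailed (shallow objective); compare
    # medians for t0s, means elsewhere
    center <- if (j == 3) stats::median(est[, j]) else mean(est[, j])
    tol <- if (j == 3) 0.35 * truth[j] else 4 * se + 0.02 * truth[j]
    expect_lt(abs(center - truth[j]), tol)
  }
})

test_that("reference-curve fit is exact on model data and validates input", {
  pts <- exactSurvivalTable(gbmParameters(),
                            standardAssayDesign("reference_photon"))
  fit <- fitReferenceCurve(pts)
  expect_equal(estimates(fit)[["alpha"]], 0.21, tolerance = 1e-10)
  expect_equal(estimates(fit)[["beta"]], 0.02, tolerance = 1e-10)

  # reordering points does not change the fit
  fit2 <- fitReferenceCurve(pts[rev(seq_len(nrow(pts))), ])
  expect_equal(estimates(fit2), estimates(fit), tolerance = 1e-12)

  expect_error(fitReferenceCurve(pts[1, ]), "insufficient")
  zeroed <- pts; zeroed$d_photon <- 0
  expect_error(fitReferenceCurve(zeroed), "invalid design")
  contaminated <- pts; contaminated$d_neutron <- 1
  expect_error(fitReferenceCurve(contaminated), "d_photon")
})

test_that("fixed-rate protraction mode shrinks the quadratic term as expected", {
  # Data generated WITH per-point protraction at 1 Gy/min must be recovered
  # when fitting in fixed_rate mode, and misfit in acute mode.
  k <- RepairKinetics()
  D <- c(1, 2, 4, 6, 8)
  G <- vapply(D / 1, gDual, numeric(1), kinetics = k, letClass = "low")
  s <- exp(-(0.21 * D + 0.02 * G * D^2))
  pts <- data.frame(condition = "reference_photon", d_boron = 0,
                    d_neutron = 0, d_photon = D, d_boron_sigma = 0,
                    surviving_fraction = s, sf_sigma = 0.05 * s,
                    duration_min = D)
  fit <- fitReferenceCurve(pts, k, protractionMode = "fixed_rate",
                           doseRate = 1)
  expect_equal(estimates(fit)[["alpha"]], 0.21, tolerance = 1e-8)
  expect_equal(estimates(fit)[["beta"]], 0.02, tolerance = 1e-8)
  fitAcute <- fitReferenceCurve(pts, k, protractionMode = "acute")
  expect_lt(estimates(fitAcute)[["beta"]], 0.02)  # G < 1 absorbed into beta
})

test_that("joint mixed-field fit recovers truth with beta_B at its bound", {
  truth <- gbmParameters()
  photon <- co60Params()
  beam <- exactSurvivalTable(truth, standardAssayDesign("beam_only"))
  bnct <- exactSurvivalTable(truth, standardAssayDesign("bpa_bnct",
                                                        boronSigmaRel = 0))
  fit <- fitMixedFieldCurves(beam, bnct, photon)
  est <- estimates(fit)
  expect_equal(est[["alpha_n"]], 0.5, tolerance = 1e-5)
  expect_equal(est[["beta_n"]], 0.5, tolerance = 1e-5)
  expect_equal(est[["alpha_B"]], 3.0, tolerance = 1e-5)
  expect_lt(est[["beta_B"]], 1e-8)
  expect_true(boundaryFlags(fit)[["beta_B"]])

  # missing conditions are rejected with informative errors
  expect_error(fitMixedFieldCurves(beam, beam, photon), "unidentifiable")
  expect_error(fitMixedFieldCurves(beam[0, ], bnct, photon), "non-empty")
  boronFree <- bnct; boronFree$d_boron <- 0
  expect_error(fitMixedFieldCurves(beam, boronFree, photon),
               "unidentifiable")
})

test_that("mixed-field fit is invariant under point reordering", {
  truth <- gbmParameters()
  beam <- exactSurvivalTable(truth, standardAssayDesign("beam_only"))
  bnct <- exactSurvivalTable(truth, standardAssayDesign("bpa_bnct",
                                                        boronSigmaRel = 0))
  f1 <- fitMixedFieldCurves(beam, bnct, co60Params())
  f2 <- fitMixedFieldCurves(beam[rev(seq_len(nrow(beam))), ],
                            bnct[rev(seq_len(nrow(bnct))), ], co60Params())
  expect_equal(estimates(f1), estimates(f2), tolerance = 1e-8)
})

test_that("releasing a non-negativity bound never increases the objective", {
  # data whose unconstrained WLS solution has beta < 0: the bounded fit must
  # sit at beta = 0 with an objective no better than the unconstrained one
  D <- c(1, 2, 4, 6, 8)
  withr::with_seed(7, {
    y <- 0.4 * D - 0.01 * D^2 + rnorm(5, 0, 0.01)  # concave log-effect
  })
  pts <- data.frame(condition = "reference_photon", d_boron = 0,
                    d_neutron = 0, d_photon = D, d_boron_sigma = 0,
                    surviving_fraction = exp(-y), sf_sigma = 0.01 * exp(-y),
                    duration_min = 0)
  fit <- fitReferenceCurve(pts)
  expect_true(boundaryFlags(fit)[["beta"]])
  expect_equal(estimates(fit)[["beta"]], 0)
  # unconstrained weighted LS on the same design
  w <- 1 / (0.01)^2
  X <- cbind(D, D^2)
  betaHat <- solve(crossprod(X, w * X), crossprod(X, w * y))
  rssFree <- sum(w * (y - X %*% betaHat)^2)
  expect_gte(fit@objective, rssFree - 1e-8)
})

test_that("confidence intervals match closed-form WLS standard errors", {
  pts <- exactSurvivalTable(gbmParameters(),
                            standardAssayDesign("reference_photon"),
                            sfSigmaRel = 0.05)
  fit <- fitReferenceCurve(pts)
  D <- pts$d_photon
  sigY <- pts$sf_sigma / pts$surviving_fraction
  X <- cbind(D, D^2)
  covRef <- solve(crossprod(X, X / sigY^2))
  ci <- confidenceIntervals(fit, level = 0.68)
  z <- qnorm(0.84)
  expect_equal(ci$halfWidth, unname(z * sqrt(diag(covRef))), tolerance = 1e-8)
  expect_equal(sigmas(fit), z * sqrt(diag(covRef)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # degenerate level
  ci0 <- confidenceIntervals(fit, level = 0)
  expect_equal(ci0$halfWidth, c(0, 0))
})

test_that("parametric bootstrap agrees with the linearized intervals", {
  truth <- gbmParameters()
  pts <- generateClonogenicAssay(truth,
                                 standardAssayDesign("reference_photon"),
                                 seed = 11)
  fit <- fitReferenceCurve(pts)
  lin <- confidenceIntervals(fit, level = 0.68, method = "linearized")
  boot <- confidenceIntervals(fit, level = 0.68, method = "bootstrap",
                              nBoot = 300L, seed = 5)
  for (i in seq_len(nrow(lin))) {
    expect_lt(abs(boot$halfWidth[i] - lin$halfWidth[i]) / lin$halfWidth[i],
              0.2)
  }
})
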