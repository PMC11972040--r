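#' @include core-models.R
NULL

# ---- internal helpers -------------------------------------------------------

# Validate a survival table (see readSurvivalTable for the column contract)
# and return it with defaults filled in.
checkSurvivalTable <- function(points) {
  req <- c("condition", "d_boron", "d_neutron", "d_photon",
           "surviving_fraction", "duration_min")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("survival table is missing columns: ", paste(miss, collapse = ", "))
  if (!"sf_sigma" %in% names(points)) points$sf_sigma <- NA_real_
  if (!"d_boron_sigma" %in% names(points)) points$d_boron_sigma <- 0
  sf <- points$surviving_fraction
  if (anyNA(sf) || any(sf <= 0) || any(sf > 1))
    stop("'surviving_fraction' must lie in (0, 1]")
  if (any(points$d_boron < 0 | points$d_neutron < 0 | points$d_photon < 0))
    stop("dose components must be >= 0")
  points
}

# Log-survival observations and weights: y = -log(S), sigma_y = sf_sigma / S.
# Points without a usable sigma get unit weight (flagged via attribute).
logSurvivalObs <- function(points) {
  y <- -log(points$surviving_fraction)
  sig <- points$sf_sigma / points$surviving_fraction
  known <- all(is.finite(sig) & sig > 0)
  w <- if (known) 1 / sig^2 else rep(1, length(y))
  list(y = y, w = w, sigmaKnown = known)
}

# Weighted least squares with non-negativity bounds on the coefficients,
# solved exactly by enumerating active sets (p is tiny here).
boundedWLS <- function(X, y, w) {
  p <- ncol(X)
  best <- NULL
  for (k in 0:(2^p - 1)) {
    fixed <- as.logical(bitwAnd(k, 2^(seq_len(p) - 1)))
    free <- !fixed
    beta <- numeric(p)
    if (any(free)) {
      Xf <- X[, free, drop = FALSE]
      fit <- tryCatch(
        solve(crossprod(Xf, w * Xf), crossprod(Xf, w * y)),
        error = function(e) NULL)
      if (is.null(fit)) next
      beta[free] <- fit
    }
    if (any(beta < -1e-12)) next
    beta[beta < 0] <- 0
    rss <- sum(w * (y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(beta = beta, rss = rss, active = fixed)
  }
  if (is.null(best)) stop("bounded weighted least squares failed")
  best
}

# Covariance of a (possibly bound-constrained) weighted LS solution.
# Known sigmas: (X'WX)^-1; unknown: scaled by RSS/(n-p). Rows/cols of
# parameters at an active bound are NA (their sampling law is one-sided).
wlsCovariance <- function(X, w, rss, n, active, sigmaKnown) {
  p <- ncol(X)
  cov <- matrix(NA_real_, p, p)
  free <- !active
  if (any(free)) {
    Xf <- X[, free, drop = FALSE]
    cf <- tryCatch(solve(crossprod(Xf, w * Xf)), error = function(e) NULL)
    if (!is.null(cf)) {
      if (!sigmaKnown) {
        df <- max(n - sum(free), 1L)
        cf <- cf * rss / df
      }
      cov[free, free] <- cf
    }
  }
  cov
}

newMLQFit <- function(estimates, covariance, objective, n, active,
                      details = list()) {
  sig <- sqrt(pmax(diag(covariance), 0))
  sig[is.na(diag(covariance))] <- NA_real_
  # 68% half-widths as conventionally quoted alongside the estimates
  hw <- stats::qnorm(0.84) * sig
  hw[active] <- 0           # parameter pinned at its bound
  hw[is.na(hw)] <- 0
  names(sig) <- names(hw) <- names(active) <- names(estimates)
  dimnames(covariance) <- list(names(estimates), names(estimates))
  MLQFit(estimates = estimates, sigmas = hw, covariance = covariance,
         objective = objective, nPoints = as.integer(n),
         boundaryFlags = active, details = details)
}

# ---- repair kinetics --------------------------------------------------------

#' Fit bi-exponential repair kinetics to a foci time series
#'
#' Error-weighted least-squares fit of the bi-exponential foci-decay model
#' (see [fociIntensity()]) with parameters `c` (fast proportion), `t0f` and
#' `t0s` (min). The objective of this model is notoriously shallow along the
#' slow component, so the fit is multi-started on a fixed grid of starting
#' values; the labels are swapped after the fit if needed so that
#' `t0f <= t0s` always holds (swapping `c` for `1 - c` accordingly).
#'
#' @param series data.frame with columns `time` (min, strictly increasing),
#'   `intensity` (normalized, first value near 1) and optionally `sigma`.
#' @param seed Integer seed controlling start-point jitter (the fit itself
#'   is deterministic given the grid; the seed is recorded for provenance).
#' @return An [MLQFit] with estimates `c`, `t0f`, `t0s`, plus `mse`
#'   (mean squared residual) in `details`.
#' @examples
#' s <- generateFociSeries(RepairKinetics(), times = seq(0, 1440, by = 120),
#'                         noiseSigma = 0, seed = 1)
#' fitRepairKinetics(s)
#' @export
fitRepairKinetics <- function(series, seed = 1L) {
  if (!all(c("time", "intensity") %in% names(series)))
    stop("'series' needs columns 'time' and 'intensity'")
  tt <- series$time
  ii <- series$intensity
  if (length(tt) < 4L)
    stop("insufficient data: need at least 4 time points for 3 parameters")
  if (is.unsorted(tt, strictly = TRUE) || tt[1] < 0)
    stop("'time' must be strictly increasing and start at >= 0")
  if (any(ii <= 0)) stop("'intensity' must be > 0")
  sig <- if ("sigma" %in% names(series)) series$sigma else rep(NA_real_, length(ii))
  sigmaKnown <- all(is.finite(sig) & sig > 0)
  w <- if (sigmaKnown) 1 / sig^2 else rep(1, length(ii))

  resid <- function(p) sqrt(w) * (ii - fociIntensity(tt, p[1], p[2], p[3]))
  lower <- c(0, 1e-3, 1e-3)
  upper <- c(1, 1e7, 1e7)
  tmax <- max(tt[length(tt)], 1)
  starts <- expand.grid(c = c(0.3, 0.6, 0.9),
                        t0f = tmax * c(0.02, 0.1, 0.3),
                        t0s = tmax * c(0.5, 1, 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-14) best <- fit
  }
  if (is.null(best)) stop("repair-kinetics fit did not converge from any start")

  p <- best$par
  if (p[2] > p[3]) p <- c(1 - p[1], p[3], p[2])   # enforce t0f <= t0s
  names(p) <- c("c", "t0f", "t0s")
  active <- c(p[1] <= lower[1] + 1e-8 | p[1] >= upper[1] - 1e-8,
              p[2] <= lower[2] * (1 + 1e-6),
              p[3] <= lower[3] * (1 + 1e-6) | p[3] >= upper[3] * (1 - 1e-6))

  J <- numDeriv2(function(q) fociIntensity(tt, q[1], q[2], q[3]), p)
  Jw <- sqrt(w) * J
  rss <- best$deviance
  covm <- matrix(NA_real_, 3, 3)
  free <- !active
  cf <- tryCatch(solve(crossprod(Jw[, free, drop = FALSE])),
                 error = function(e) NULL)
  if (!is.null(cf)) {
    if (!sigmaKnown) cf <- cf * rss / max(length(tt) - sum(free), 1L)
    covm[free, free] <- cf
  }
  res <- ii - fociIntensity(tt, p[1], p[2], p[3])
  boot <- makeBootstrapper(
    simulate = function(s) {
      noise <- if (sigmaKnown) sig else rep(sqrt(mean(res^2)), length(ii))
      pmax(fociIntensity(tt, p[1], p[2], p[3]) +
             stats::rnorm(length(ii), 0, noise), 1e-6)
    },
    refit = function(iNew) {
      d <- data.frame(time = tt, intensity = iNew)
      if (sigmaKnown) d$sigma <- sig
      estimates(fitRepairKinetics(d, seed = seed))
    })
  newMLQFit(p, covm, rss, length(tt), active,
            details = list(mse = mean(res^2), seed = seed,
                           model = "biexponential-foci", bootstrap = boot))
}

# Forward-difference Jacobian (central where affordable); small helper so
# the fitting code does not depend on an external numeric-derivative package.
numDeriv2 <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- max(p[j] - h, 0)
    J[, j] <- (f(pp) - f(pm)) / (pp[j] - pm[j])
  }
  J
}

makeBootstrapper <- function(simulate, refit) {
  function(nBoot = 200L, seed = 1L) {
    withr::with_seed(seed, {
      out <- NULL
      for (b in seq_len(nBoot)) {
        est <- tryCatch(refit(simulate(b)), error = function(e) NULL)
        if (!is.null(est)) out <- rbind(out, est)
      }
      out
    })
  }
}

# ---- reference photon curve -------------------------------------------------

#' Fit the reference photon survival curve
#'
#' Error-weighted least squares of the reference MLQ model on log-survival,
#' which is linear in (alpha, beta): `-log S = alpha D + beta G D^2`.
#' Weights come from the survival uncertainties (`sigma_y = sf_sigma / S`).
#' Non-negativity of alpha and beta is enforced exactly (active-set
#' solution). In `"acute"` protraction mode G = 1 for every point; in
#' `"fixed_rate"` mode each point's delivery time is `D / doseRate` and G is
#' the low-LET dual-kinetics factor for that time.
#'
#' @param points Survival table (see [readSurvivalTable()]) with
#'   `condition == "reference_photon"` rows: only `d_photon` is nonzero.
#' @param kinetics [RepairKinetics] (needed in `"fixed_rate"` mode).
#' @param protractionMode `"acute"` (default) or `"fixed_rate"`.
#' @param doseRate Gy/min, used in `"fixed_rate"` mode.
#' @param weightMode `"vertical"` (default) uses survival uncertainties
#'   only; `"effective"` additionally folds per-point dose uncertainties
#'   into the weights via the model gradient (one reweighted refit).
#' @return An [MLQFit] with estimates `alpha`, `beta`.
#' @export
fitReferenceCurve <- function(points, kinetics = RepairKinetics(),
                              protractionMode = c("acute", "fixed_rate"),
                              doseRate = 1,
                              weightMode = c("vertical", "effective")) {
  protractionMode <- match.arg(protractionMode)
  weightMode <- match.arg(weightMode)
  points <- checkSurvivalTable(points)
  if (any(points$d_boron > 0) || any(points$d_neutron > 0))
    stop("reference photon points must have only 'd_photon' nonzero")
  D <- points$d_photon
  if (all(D == 0)) stop("invalid design: all doses are zero")
  if (sum(D > 0) < 3L)
    stop("insufficient data: need at least 3 nonzero-dose points")

  G <- if (protractionMode == "acute") rep(1, length(D))
       else vapply(D / doseRate, gDual, numeric(1), kinetics = kinetics,
                   letClass = "low")
  obs <- logSurvivalObs(points)
  X <- cbind(alpha = D, beta = G * D^2)
  sol <- boundedWLS(X, obs$y, obs$w)
  if (weightMode == "effective") {
    # effective-variance reweighting: add the dose-error contribution
    # (d y / d D)^2 sigma_D^2 evaluated at the current estimates
    dydD <- sol$beta[1] + 2 * sol$beta[2] * G * D
    sigY2 <- 1 / obs$w + (dydD * points$d_boron_sigma * 0)^2  # photon-only
    if ("d_photon_sigma" %in% names(points))
      sigY2 <- sigY2 + (dydD * points$d_photon_sigma)^2
    w2 <- 1 / sigY2
    sol <- boundedWLS(X, obs$y, w2)
    obs$w <- w2
  }
  est <- c(alpha = sol$beta[1], beta = sol$beta[2])
  covm <- wlsCovariance(X, obs$w, sol$rss, length(D), sol$active,
                        obs$sigmaKnown)
  fitted <- as.numeric(X %*% sol$beta)
  boot <- makeBootstrapper(
    simulate = function(b) {
      sigY <- 1 / sqrt(obs$w)
      exp(-(fitted + stats::rnorm(length(fitted), 0, sigY)))
    },
    refit = function(sNew) {
      p2 <- points
      p2$surviving_fraction <- pmin(pmax(sNew, 1e-12), 1)
      p2$sf_sigma <- (1 / sqrt(obs$w)) * p2$surviving_fraction
      estimates(fitReferenceCurve(p2, kinetics, protractionMode, doseRate))
    })
  newMLQFit(est, covm, sol$rss, length(D), sol$active,
            details = list(model = "reference-mlq", g = G,
                           protractionMode = protractionMode,
                           bootstrap = boot))
}

# ---- mixed-field curves -----------------------------------------------------

#' Jointly fit beam-only and BPA-BNCT survival curves
#'
#' Simultaneous error-weighted fit of the mixed-field MLQ model to the
#' beam-only curve (neutron + photon contamination, no boron) and the
#' BPA-BNCT curve (all three components), with the photon parameters held
#' fixed at the reference-radiation fit (the gamma component of the mixed
#' field is assumed to behave like the reference photons). The two
#' conditions share (alpha_n, beta_n); (alpha_B, beta_B) are informed only
#' by the BNCT points. Non-negativity bounds are enforced; the betas are
#' parameterized internally on the square-root scale so the
#' `sqrt(beta_i beta_j)` synergy terms stay smooth at the `beta = 0` bound,
#' and are reported on the natural scale with delta-method sigmas.
#'
#' @param beamOnly,bnct Survival tables (see [readSurvivalTable()]) for the
#'   two conditions; `beamOnly` must have zero boron dose, `bnct` nonzero
#'   boron dose.
#' @param photonParams [LQParameters] of the photon component (fixed).
#' @param kinetics [RepairKinetics] for the per-point G factors.
#' @param seed Integer; recorded for provenance (the multi-start grid is
#'   fixed).
#' @return An [MLQFit] with estimates `alpha_n`, `beta_n`, `alpha_B`,
#'   `beta_B`.
#' @export
fitMixedFieldCurves <- function(beamOnly, bnct, photonParams,
                                kinetics = RepairKinetics(), seed = 1L) {
  beamOnly <- checkSurvivalTable(beamOnly)
  bnct <- checkSurvivalTable(bnct)
  stopifnot(is(photonParams, "LQParameters"))
  if (nrow(beamOnly) == 0L || nrow(bnct) == 0L)
    stop("both 'beamOnly' and 'bnct' curve sets must be non-empty")
  if (any(beamOnly$d_boron > 0))
    stop("beam-only points must have zero boron dose")
  if (all(bnct$d_boron == 0))
    stop("unidentifiable: BNCT points carry no boron dose, ",
         "boron parameters cannot be estimated")

  pts <- rbind(beamOnly, bnct)
  obs <- logSurvivalObs(pts)
  aG <- photonParams@alpha
  bG <- photonParams@beta
  gPer <- lapply(pts$duration_min, mixedFieldGFactors, kinetics = kinetics)

  predict <- function(q) {
    # q = (alpha_n, sqrt(beta_n), alpha_B, sqrt(beta_B))
    vapply(seq_len(nrow(pts)), function(i) {
      mixedFieldLogEffect(
        dB = pts$d_boron[i], dN = pts$d_neutron[i], dG = pts$d_photon[i],
        aB = q[3], bB = q[4]^2, aN = q[1], bN = q[2]^2,
        aG = aG, bG = bG, g = gPer[[i]])
    }, numeric(1))
  }
  resid <- function(q) sqrt(obs$w) * (obs$y - predict(q))

  lower <- rep(0, 4)
  upper <- c(50, 10, 50, 10)
  starts <- expand.grid(aN = c(0.1, 0.5, 1.5), sN = c(0.2, 0.8),
                        aB = c(1, 3), sB = c(0.01, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(as.numeric(starts[i, ]), lower = lower,
                         upper = upper, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-14) best <- fit
  }
  if (is.null(best)) stop("mixed-field fit did not converge from any start")

  q <- best$par
  est <- c(alpha_n = q[1], beta_n = q[2]^2, alpha_B = q[3], beta_B = q[4]^2)
  activeQ <- q <= lower + 1e-7
  active <- activeQ  # same positions after the square transform
  names(active) <- names(est)

  # covariance on the sqrt scale, then delta method to the natural scale
  J <- numDeriv2(predict, q)
  Jw <- sqrt(obs$w) * J
  covQ <- matrix(NA_real_, 4, 4)
  free <- !activeQ
  cf <- tryCatch(solve(crossprod(Jw[, free, drop = FALSE])),
                 error = function(e) NULL)
  if (!is.null(cf)) {
    if (!obs$sigmaKnown)
      cf <- cf * best$deviance / max(nrow(pts) - sum(free), 1L)
    covQ[free, free] <- cf
  }
  Tm <- diag(c(1, 2 * q[2], 1, 2 * q[4]))
  covm <- Tm %*% covQ %*% t(Tm)

  fitted <- predict(q)
  nBeam <- nrow(beamOnly)
  boot <- makeBootstrapper(
    simulate = function(b) {
      sigY <- 1 / sqrt(obs$w)
      exp(-(fitted + stats::rnorm(length(fitted), 0, sigY)))
    },
    refit = function(sNew) {
      p2 <- pts
      p2$surviving_fraction <- pmin(pmax(sNew, 1e-12), 1)
      p2$sf_sigma <- (1 / sqrt(obs$w)) * p2$surviving_fraction
      estimates(fitMixedFieldCurves(p2[seq_len(nBeam), ],
                                    p2[-seq_len(nBeam), ],
                                    photonParams, kinetics, seed))
    })
  newMLQFit(est, covm, best$deviance, nrow(pts), active,
            details = list(model = "mixed-field-mlq", seed = seed,
                           photonParams = c(alpha = aG, beta = bG),
                           bootstrap = boot))
}

# ---- confidence intervals ---------------------------------------------------

#' @describeIn confidenceIntervals Per-parameter confidence intervals from
#'   the linearized covariance (default) or a seeded parametric bootstrap.
#'   Parameters sitting at a non-negativity bound get one-sided intervals
#'   (`lower = estimate`). A singular covariance direction is reported as
#'   `NA` rather than a number.
#' @param method `"linearized"` or `"bootstrap"`.
#' @param nBoot Bootstrap replicates (bootstrap method only).
#' @param seed Seed for the parametric bootstrap.
#' @return data.frame with columns `parameter`, `estimate`, `halfWidth`,
#'   `lower`, `upper`, `atBound`.
#' @export
setMethod("confidenceIntervals", "MLQFit",
  function(fit, level = 0.68, method = c("linearized", "bootstrap"),
           nBoot = 200L, seed = 1L) {
    method <- match.arg(method)
    if (level < 0 || level >= 1) stop("'level' must lie in [0, 1)")
    est <- fit@estimates
    if (method == "linearized") {
      se <- sqrt(pmax(diag(fit@covariance), 0))
    } else {
      booter <- fit@details$bootstrap
      if (is.null(booter))
        stop("this fit does not carry a bootstrap simulator")
      mat <- booter(nBoot = nBoot, seed = seed)
      se <- apply(mat, 2, stats::sd)[names(est)]
    }
    z <- stats::qnorm((1 + level) / 2)
    hw <- z * se
    atBound <- fit@boundaryFlags
    lower <- est - hw
    upper <- est + hw
    # one-sided for bound-constrained parameters at the bound
    z1 <- stats::qnorm(level)
    lower[atBound] <- est[atBound]
    upper[atBound] <- est[atBound] + z1 * ifelse(is.na(se[atBound]), 0,
                                                 se[atBound])
    hw[atBound] <- upper[atBound] - est[atBound]
    data.frame(parameter = names(est), estimate = unname(est),
               halfWidth = unname(hw), lower = unname(lower),
               upper = unname(upper), atBound = unname(atBound),
               row.names = NULL)
  })
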