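#' @include grids-reporting.R
NULL

#' Standard assay designs for the three irradiation conditions
#'
#' Convenience constructors of [AssayDesign] objects matching the study
#' conditions the generators emulate: reference photon irradiations at
#' about 1 Gy/min delivering a fixed dose ladder, and 10-min reactor
#' irradiations whose dose scales with reactor power (four power steps),
#' with ~10% of the beam-only point dose carried by photon contamination.
#' Cells seeded per flask increase with dose so colony counts stay
#' countable, as in standard clonogenic practice.
#'
#' @param condition One of `"reference_photon"`, `"beam_only"`,
#'   `"bpa_bnct"`.
#' @param photonContaminationFrac Fraction of the total beam-only/BNCT
#'   point dose carried by photons (default 0.1).
#' @param boronSigmaRel Relative boron-dose uncertainty for BNCT points
#'   (default 0.05, dominated in practice by the boron-concentration
#'   measurement).
#' @return An [AssayDesign].
#' @examples
#' standardAssayDesign("reference_photon")
#' @export
standardAssayDesign <- function(condition = c("reference_photon", "beam_only",
                                              "bpa_bnct"),
                                photonContaminationFrac = 0.1,
                                boronSigmaRel = 0.05) {
  condition <- match.arg(condition)
  if (condition == "reference_photon") {
    D <- c(1, 2, 4, 6, 8)
    AssayDesign(
      condition = condition,
      doses = data.frame(boron = 0, neutron = 0, photon = D),
      durationMin = 0,          # ~1 Gy/min; treated as acute for fitting
      cellsSeeded = c(200, 400, 1000, 3000, 8000),
      platingEfficiency = 0.7, replicates = 3L, boronSigmaRel = 0)
  } else if (condition == "beam_only") {
    # four reactor powers, 10-min irradiations; total point doses ~0.8-6 Gy
    total <- c(0.8, 1.6, 3.2, 6.0)
    AssayDesign(
      condition = condition,
      doses = data.frame(boron = 0,
                         neutron = total * (1 - photonContaminationFrac),
                         photon = total * photonContaminationFrac),
      durationMin = 10,
      cellsSeeded = c(300, 600, 2000, 10000),
      platingEfficiency = 0.7, replicates = 3L, boronSigmaRel = 0)
  } else {
    # same beam, with boron: the boron component dominates the point dose
    total <- c(0.8, 1.6, 3.2, 6.0)
    AssayDesign(
      condition = condition,
      doses = data.frame(boron = total * 1.2,
                         neutron = total * (1 - photonContaminationFrac),
                         photon = total * photonContaminationFrac),
      durationMin = 10,
      cellsSeeded = c(2000, 10000, 50000, 300000),
      platingEfficiency = 0.7, replicates = 3L, boronSigmaRel = boronSigmaRel)
  }
}

#' Generate a synthetic clonogenic assay
#'
#' Simulates colony counts for a clonogenic survival assay under the
#' mixed-field MLQ model. Per dose point and replicate, the expected
#' survival is computed with [survivalMixedField()] for the point's
#' protocol; colonies are drawn as
#' `Poisson(cellsSeeded * platingEfficiency * S)`; the reported surviving
#' fraction is the replicate-pooled colony count divided by
#' `cellsSeeded * platingEfficiency`, with a Poisson standard error. The
#' nominal boron dose is perturbed by a relative Gaussian error
#' (`boronSigmaRel`), emulating the boron-concentration measurement
#' uncertainty; the *reported* dose is the perturbed (measured) one. Fully
#' reproducible given the seed.
#'
#' @param truth [RadiobiologicalParameterSet] generating the data.
#' @param design [AssayDesign].
#' @param seed Integer seed.
#' @return A survival table (data.frame) with the columns of
#'   [readSurvivalTable()].
#' @examples
#' generateClonogenicAssay(gbmParameters(),
#'                         standardAssayDesign("reference_photon"), seed = 1)
#' @export
generateClonogenicAssay <- function(truth, design, seed = 1L) {
  stopifnot(is(truth, "RadiobiologicalParameterSet"),
            is(design, "AssayDesign"))
  validObject(design)
  n <- nrow(design@doses)
  dur <- rep_len(design@durationMin, n)
  seeded <- rep_len(design@cellsSeeded, n)
  pe <- design@platingEfficiency
  reps <- design@replicates

  withr::with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      dB <- design@doses$boron[i]
      dBMeas <- if (design@boronSigmaRel > 0 && dB > 0)
        max(dB * (1 + stats::rnorm(1, 0, design@boronSigmaRel)), 0) else dB
      s <- survivalMixedField(
        MixedFieldDose(dB, design@doses$neutron[i], design@doses$photon[i]),
        truth, protocol = dur[i])
      lambda <- seeded[i] * pe * s
      colonies <- stats::rpois(reps, lambda)
      tot <- sum(colonies)
      denom <- reps * seeded[i] * pe
      sf <- tot / denom
      sfSigma <- sqrt(max(tot, 1)) / denom
      data.frame(
        condition = design@condition,
        d_boron = dBMeas, d_neutron = design@doses$neutron[i],
        d_photon = design@doses$photon[i],
        d_boron_sigma = design@boronSigmaRel * dBMeas,
        surviving_fraction = max(sf, 0.5 / denom),  # keep in (0, 1]
        sf_sigma = sfSigma,
        duration_min = dur[i],
        colonies = tot, cells_seeded = reps * seeded[i]
      )
    })
    out <- do.call(rbind, out)
  })
  if (all(seeded * pe * 1 < 1))
    stop("degenerate design: expected colonies < 1 at every point")
  out$surviving_fraction <- pmin(out$surviving_fraction, 1)
  out
}

#' Generate a synthetic foci-decay time series
#'
#' Bi-exponential repair intensity (see [fociIntensity()]) with additive
#' Gaussian noise, clipped at a small positive floor and re-normalized so
#' the first intensity is 1. Deterministic given the seed.
#'
#' @param kinetics [RepairKinetics] truth; its low-LET fast fraction is the
#'   bi-exponential `c`.
#' @param times Sampling times (min), `>= 0`, strictly increasing.
#' @param noiseSigma Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed.
#' @return data.frame with `time`, `intensity`, `sigma`.
#' @examples
#' generateFociSeries(RepairKinetics(), seq(0, 1440, by = 120), 0.05, 1)
#' @export
generateFociSeries <- function(kinetics = RepairKinetics(),
                               times = seq(0, 1440, by = 120),
                               noiseSigma = 0.05, seed = 1L) {
  stopifnot(is(kinetics, "RepairKinetics"))
  if (length(times) == 0L) stop("invalid design: 'times' is empty")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("'times' must be >= 0 and strictly increasing")
  mu <- fociIntensity(times, fracFast(kinetics, "low"),
                      kinetics@t0Fast, kinetics@t0Slow)
  withr::with_seed(seed, {
    ii <- mu + stats::rnorm(length(mu), 0, noiseSigma)
  })
  ii <- pmax(ii, 1e-4)
  ii <- ii / ii[1]
  data.frame(time = times, intensity = ii,
             sigma = rep(max(noiseSigma, 1e-6), length(times)))
}

#' Generate a synthetic phantom dose-component field
#'
#' Builds a rate-mode [DoseComponentField] on a rectangular water-equivalent
#' block: each component's dose rate starts at its surface value and decays
#' exponentially along the beam axis with its attenuation length, modulated
#' by small seeded multiplicative log-normal noise. The boron grid is
#' emitted per ppm. Also rasterizes a spherical tumor ROI and the
#' complementary normal-tissue (brain) ROI with their boron concentrations.
#' Deterministic given the seed.
#'
#' @param spec [PhantomSpec].
#' @param seed Integer seed.
#' @param noiseRel Relative (log-normal) noise of the grids (default 0.02;
#'   0 gives the noise-free field).
#' @return List with `field` ([DoseComponentField]) and `rois` (list of
#'   [ROIMask]: `tumor`, `brain`).
#' @examples
#' ph <- generatePhantomField(PhantomSpec(), seed = 1)
#' ph$field
#' @export
generatePhantomField <- function(spec = PhantomSpec(), seed = 1L,
                                 noiseRel = 0.02) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape
  ax <- spec@beamAxis
  # depth (cm) of each voxel centre along the beam axis
  depth <- ((seq_len(d[ax]) - 0.5) * spec@spacing[ax]) / 10
  comps <- c("boronPerPpm", "thermalNeutron", "fastNeutron", "photon")
  grids <- withr::with_seed(seed, {
    lapply(comps, function(cmp) {
      prof <- spec@surfaceDoseRates[[cmp]] *
        exp(-depth / spec@attenuationLengths[[cmp]])
      g <- array(0, d)
      idx <- slice.index(g, ax)
      g[] <- prof[idx]
      if (noiseRel > 0)
        g <- g * exp(stats::rnorm(length(g), 0, noiseRel))
      g
    })
  })
  names(grids) <- comps
  field <- DoseComponentField(
    boronPerPpm = grids$boronPerPpm, thermalNeutron = grids$thermalNeutron,
    fastNeutron = grids$fastNeutron, photon = grids$photon,
    spacing = spec@spacing, origin = c(0, 0, 0), unitsMode = "rate")

  ctr <- (spec@tumorCenter - 0.5) * spec@spacing
  coord <- function(axis) ((seq_len(d[axis]) - 0.5) * spec@spacing[axis])
  dx <- coord(1) - ctr[1]
  dy <- coord(2) - ctr[2]
  dz <- coord(3) - ctr[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  tumorMask <- r2 <= spec@tumorRadius^2
  if (!any(tumorMask)) stop("invalid spec: tumor sphere contains no voxel")
  rois <- list(
    tumor = ROIMask(mask = tumorMask, name = "GTV",
                    boronConcentration = spec@boronTumorPpm),
    brain = ROIMask(mask = !tumorMask, name = "brain",
                    boronConcentration = spec@boronBrainPpm)
  )
  list(field = field, rois = rois)
}
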