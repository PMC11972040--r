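#' @include AllGenerics.R
NULL

## ---- RepairKinetics ---------------------------------------------------------

#' Dual-kinetics sub-lethal damage repair parameters
#'
#' Characteristic repair times of the fast and slow first-order repair
#' components, together with the proportion of sub-lesions repaired by the
#' fast kinetics for low-LET and for high-LET radiation. The slow proportion
#' is `1 - fast` by construction. Times are in minutes.
#'
#' The defaults are the U87 glioblastoma values: repair times fitted from
#' bi-exponential foci-decay kinetics (t0 fast = 91 min, t0 slow = 1238 min,
#' low-LET fast fraction 0.77) and the high-LET fast fraction 0.2 taken from
#' the dual-kinetics MLQ literature.
#'
#' @slot t0Fast Fast characteristic repair time (min).
#' @slot t0Slow Slow characteristic repair time (min).
#' @slot fracFastLowLET Proportion of sub-lesions repaired with the fast
#'   kinetics for low-LET radiation (photons), in \[0, 1\].
#' @slot fracFastHighLET Same proportion for high-LET radiation (neutrons,
#'   boron capture products), in \[0, 1\].
#'
#' @param t0Fast,t0Slow,fracFastLowLET,fracFastHighLET See slots.
#' @return `RepairKinetics()` returns a `RepairKinetics` object.
#' @examples
#' k <- RepairKinetics()
#' fracFast(k, "high")
#' @export RepairKinetics
#' @exportClass RepairKinetics
setClass("RepairKinetics",
  representation(
    t0Fast = "numeric",
    t0Slow = "numeric",
    fracFastLowLET = "numeric",
    fracFastHighLET = "numeric"
  ),
  prototype(
    t0Fast = 91, t0Slow = 1238,
    fracFastLowLET = 0.77, fracFastHighLET = 0.2
  )
)

RepairKinetics <- function(t0Fast = 91, t0Slow = 1238,
                           fracFastLowLET = 0.77, fracFastHighLET = 0.2) {
  new("RepairKinetics", t0Fast = as.numeric(t0Fast),
      t0Slow = as.numeric(t0Slow),
      fracFastLowLET = as.numeric(fracFastLowLET),
      fracFastHighLET = as.numeric(fracFastHighLET))
}

setValidity("RepairKinetics", function(object) {
  msg <- character()
  for (s in c("t0Fast", "t0Slow", "fracFastLowLET", "fracFastHighLET"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
  if (length(msg)) return(msg)
  if (object@t0Fast <= 0) msg <- c(msg, "'t0Fast' must be > 0")
  if (object@t0Fast > object@t0Slow)
    msg <- c(msg, "'t0Fast' must not exceed 't0Slow'")
  for (s in c("fracFastLowLET", "fracFastHighLET"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
  if (length(msg)) msg else TRUE
})

#' @describeIn RepairKinetics Fast-kinetics proportion for a LET class
#'   (`"low"` or `"high"`); the slow proportion is its complement.
#' @param object,x A `RepairKinetics` object.
#' @export
fracFast <- function(object, letClass = c("low", "high")) {
  letClass <- match.arg(letClass)
  if (letClass == "low") object@fracFastLowLET else object@fracFastHighLET
}

#' @describeIn RepairKinetics Fast repair time (min).
#' @export
t0Fast <- function(object) object@t0Fast

#' @describeIn RepairKinetics Slow repair time (min).
#' @export
t0Slow <- function(object) object@t0Slow

setMethod("show", "RepairKinetics", function(object) {
  cat("RepairKinetics: t0 fast =", object@t0Fast, "min, t0 slow =",
      object@t0Slow, "min\n")
  cat("  fast fraction: low LET", object@fracFastLowLET,
      "| high LET", object@fracFastHighLET, "\n")
})

## ---- LQParameters -----------------------------------------------------------

#' Linear-quadratic radiobiological parameters
#'
#' An alpha/beta pair for one radiation component, tagged with the LET class
#' that selects which fast/slow repair proportions of [RepairKinetics] apply
#' when protraction factors are computed.
#'
#' @slot alpha Linear coefficient (Gy^-1), non-negative.
#' @slot beta Quadratic coefficient (Gy^-2), non-negative.
#' @slot letClass `"low"` (photons) or `"high"` (neutrons, boron capture
#'   products).
#'
#' @param alpha,beta,letClass See slots.
#' @examples
#' co60 <- LQParameters(0.21, 0.02, "low")
#' alpha(co60)
#' @export LQParameters
#' @exportClass LQParameters
setClass("LQParameters",
  representation(alpha = "numeric", beta = "numeric", letClass = "character"),
  prototype(alpha = 0, beta = 0, letClass = "low")
)

LQParameters <- function(alpha = 0, beta = 0, letClass = c("low", "high")) {
  new("LQParameters", alpha = as.numeric(alpha), beta = as.numeric(beta),
      letClass = match.arg(letClass))
}

setValidity("LQParameters", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha) || object@alpha < 0)
    msg <- c(msg, "'alpha' must be a finite scalar >= 0")
  if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta < 0)
    msg <- c(msg, "'beta' must be a finite scalar >= 0")
  if (length(object@letClass) != 1L || !object@letClass %in% c("low", "high"))
    msg <- c(msg, "'letClass' must be \"low\" or \"high\"")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("alpha", "LQParameters", function(object) object@alpha)

#' @rdname accessors
#' @export
setMethod("beta", "LQParameters", function(object) object@beta)

#' @rdname accessors
#' @export
setMethod("letClass", "LQParameters", function(object) object@letClass)

setMethod("show", "LQParameters", function(object) {
  cat(sprintf("LQParameters (%s LET): alpha = %g Gy^-1, beta = %g Gy^-2\n",
              object@letClass, object@alpha, object@beta))
})

## ---- IrradiationProtocol ----------------------------------------------------

#' Irradiation delivery protocol
#'
#' Constant-dose-rate delivery over a fixed duration theta (minutes). A
#' duration of zero encodes the acute limit, for which every Lea-Catcheside
#' factor equals 1. `doseRate` (Gy/min) is only needed when a reference
#' photon irradiation is protracted at a fixed rate, so that the delivery
#' time of a dose D is D / doseRate.
#'
#' @slot duration Delivery time theta (min); 0 means acute.
#' @slot doseRate Dose rate (Gy/min) for reference-radiation protraction;
#'   `NA` when not applicable.
#'
#' @param duration,doseRate See slots.
#' @examples
#' IrradiationProtocol(10)     # the 10-min reactor irradiations
#' IrradiationProtocol(0)      # acute exposure
#' @export IrradiationProtocol
#' @exportClass IrradiationProtocol
setClass("IrradiationProtocol",
  representation(duration = "numeric", doseRate = "numeric"),
  prototype(duration = 0, doseRate = NA_real_)
)

IrradiationProtocol <- function(duration = 0, doseRate = NA_real_) {
  new("IrradiationProtocol", duration = as.numeric(duration),
      doseRate = as.numeric(doseRate))
}

setValidity("IrradiationProtocol", function(object) {
  msg <- character()
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration < 0)
    msg <- c(msg, "'duration' must be a finite scalar >= 0")
  if (length(object@doseRate) != 1L ||
      (!is.na(object@doseRate) && object@doseRate <= 0))
    msg <- c(msg, "'doseRate' must be NA or > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("duration", "IrradiationProtocol", function(object) object@duration)

#' @rdname accessors
#' @export
setMethod("doseRate", "IrradiationProtocol", function(object) object@doseRate)

setMethod("show", "IrradiationProtocol", function(object) {
  if (object@duration == 0) cat("IrradiationProtocol: acute\n")
  else cat("IrradiationProtocol: constant rate over", object@duration, "min\n")
})

## ---- MixedFieldDose ---------------------------------------------------------

#' Mixed-field dose components
#'
#' Absorbed doses (Gy) of the three model components of a BNCT irradiation:
#' boron capture products, neutron-induced charged particles, and photons.
#' Components may be equal-length vectors, which the survival and
#' photon-equivalent functions treat element-wise (e.g. voxel lists).
#'
#' @slot boron Boron-capture dose D_B (Gy).
#' @slot neutron Neutron dose D_n (Gy).
#' @slot photon Photon dose D_gamma (Gy).
#'
#' @param boron,neutron,photon See slots; recycled to a common length.
#' @examples
#' MixedFieldDose(boron = 10, neutron = 2, photon = 1)
#' @export MixedFieldDose
#' @exportClass MixedFieldDose
MixedFieldDose <- function(boron = 0, neutron = 0, photon = 0) {
  n <- max(length(boron), length(neutron), length(photon))
  new("MixedFieldDose",
      boron = rep_len(as.numeric(boron), n),
      neutron = rep_len(as.numeric(neutron), n),
      photon = rep_len(as.numeric(photon), n))
}

setClass("MixedFieldDose",
  representation(boron = "numeric", neutron = "numeric", photon = "numeric"),
  prototype(boron = 0, neutron = 0, photon = 0)
)

setValidity("MixedFieldDose", function(object) {
  msg <- character()
  n <- length(object@boron)
  if (length(object@neutron) != n || length(object@photon) != n)
    msg <- c(msg, "component vectors must have equal length")
  if (anyNA(c(object@boron, object@neutron, object@photon)) ||
      any(c(object@boron, object@neutron, object@photon) < 0))
    msg <- c(msg, "all dose components must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("doseComponents", "MixedFieldDose", function(object)
  data.frame(boron = object@boron, neutron = object@neutron,
             photon = object@photon))

#' @rdname accessors
#' @export
setMethod("totalDose", "MixedFieldDose", function(object)
  object@boron + object@neutron + object@photon)

setMethod("show", "MixedFieldDose", function(object) {
  n <- length(object@boron)
  if (n == 1L)
    cat(sprintf("MixedFieldDose: D_B = %g, D_n = %g, D_gamma = %g Gy\n",
                object@boron, object@neutron, object@photon))
  else
    cat(sprintf("MixedFieldDose: %d points, mean total %.3g Gy\n",
                n, mean(totalDose(object))))
})

## ---- RadiobiologicalParameterSet -------------------------------------------

#' Complete radiobiological parameter set for photon-equivalent dosimetry
#'
#' Bundles the per-component linear-quadratic parameters (photon, neutron,
#' boron) with the repair kinetics and a provenance label. The photon
#' component must be low LET; neutron and boron must be high LET.
#'
#' @slot photon,neutron,boron [LQParameters] per component.
#' @slot kinetics [RepairKinetics].
#' @slot label Free-text provenance tag (e.g. `"GBM-U87/Co-60"`).
#'
#' @param photon,neutron,boron,kinetics,label See slots.
#' @examples
#' gbmParameters()          # the U87 glioblastoma set, Co-60 reference
#' @export RadiobiologicalParameterSet
#' @exportClass RadiobiologicalParameterSet
RadiobiologicalParameterSet <- setClass("RadiobiologicalParameterSet",
  representation(
    photon = "LQParameters",
    neutron = "LQParameters",
    boron = "LQParameters",
    kinetics = "RepairKinetics",
    label = "character"
  ),
  prototype(label = "unlabelled")
)

setValidity("RadiobiologicalParameterSet", function(object) {
  msg <- character()
  if (object@photon@letClass != "low")
    msg <- c(msg, "photon component must be low LET")
  if (object@neutron@letClass != "high")
    msg <- c(msg, "neutron component must be high LET")
  if (object@boron@letClass != "high")
    msg <- c(msg, "boron component must be high LET")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("kinetics", "RadiobiologicalParameterSet",
          function(object) object@kinetics)

#' @describeIn RadiobiologicalParameterSet Extract one component's
#'   [LQParameters] (`"photon"`, `"neutron"` or `"boron"`).
#' @param component Component name.
#' @export
componentParameters <- function(object, component = c("photon", "neutron", "boron")) {
  component <- match.arg(component)
  slot(object, component)
}

setMethod("show", "RadiobiologicalParameterSet", function(object) {
  cat("RadiobiologicalParameterSet:", object@label, "\n")
  for (comp in c("photon", "neutron", "boron")) {
    p <- slot(object, comp)
    cat(sprintf("  %-7s alpha = %5.3g Gy^-1, beta = %5.3g Gy^-2 (%s LET)\n",
                comp, p@alpha, p@beta, p@letClass))
  }
  cat(sprintf("  repair: t0f = %g min, t0s = %g min\n",
              object@kinetics@t0Fast, object@kinetics@t0Slow))
})

#' Built-in glioblastoma (U87) parameter set
#'
#' The radiobiological parameter set for human glioblastoma fitted from U87
#' clonogenic survival with Co-60 photons as the reference radiation:
#' photon alpha = 0.21 Gy^-1, beta = 0.02 Gy^-2; neutron alpha = 0.5,
#' beta = 0.5; boron alpha = 3.0, beta = 0, with the U87 dual-kinetics
#' repair times.
#'
#' @param kinetics Repair kinetics; defaults to the U87 values.
#' @return A [RadiobiologicalParameterSet].
#' @export
gbmParameters <- function(kinetics = RepairKinetics()) {
  RadiobiologicalParameterSet(
    photon = LQParameters(0.21, 0.02, "low"),
    neutron = LQParameters(0.5, 0.5, "high"),
    boron = LQParameters(3.0, 0.0, "high"),
    kinetics = kinetics,
    label = "GBM-U87/Co-60"
  )
}

## ---- RBEWeights -------------------------------------------------------------

#' Fixed RBE/CBE weighting factors
#'
#' Weights of the linear (RBE-weighted) photon-equivalent model: each dose
#' component in Gy is multiplied by its factor. The defaults are the factors
#' used clinically for glioblastoma BNCT (neutron RBE 3.2, boron CBE 3.8,
#' photon 1).
#'
#' @slot boron CBE factor for the boron component (> 0).
#' @slot neutron RBE factor for the neutron component (> 0).
#' @slot photon Weight of the photon component (> 0, usually 1).
#' @slot label Provenance tag.
#'
#' @param boron,neutron,photon,label See slots.
#' @examples
#' RBEWeights()                       # clinical factors
#' RBEWeights(1, 1, 1, "physical")    # physical dose
#' @export RBEWeights
#' @exportClass RBEWeights
setClass("RBEWeights",
  representation(boron = "numeric", neutron = "numeric", photon = "numeric",
                 label = "character"),
  prototype(boron = 3.8, neutron = 3.2, photon = 1, label = "clinic")
)

RBEWeights <- function(boron = 3.8, neutron = 3.2, photon = 1,
                       label = "clinic") {
  new("RBEWeights", boron = as.numeric(boron), neutron = as.numeric(neutron),
      photon = as.numeric(photon), label = label)
}

setValidity("RBEWeights", function(object) {
  w <- c(object@boron, object@neutron, object@photon)
  if (length(w) != 3L || anyNA(w) || any(w <= 0))
    "all weights must be finite scalars > 0"
  else TRUE
})

setMethod("show", "RBEWeights", function(object) {
  cat(sprintf("RBEWeights (%s): CBE(B) = %g, RBE(n) = %g, photon = %g\n",
              object@label, object@boron, object@neutron, object@photon))
})

## ---- MLQFit -----------------------------------------------------------------

#' Result of an MLQ or repair-kinetics model fit
#'
#' Parameter estimates with 68% confidence half-widths, the parameter
#' covariance (linearized, on the natural scale), the weighted residual sum
#' of squares, and per-parameter indicators of an active non-negativity
#' bound. Bound-constrained parameters sitting at their bound get one-sided
#' intervals from [confidenceIntervals()].
#'
#' @slot estimates Named numeric parameter estimates.
#' @slot sigmas Named 68% confidence half-widths (same order).
#' @slot covariance Parameter covariance matrix (may contain `NA` rows for
#'   parameters at a bound).
#' @slot objective Weighted residual sum of squares at the optimum.
#' @slot nPoints Number of data points used.
#' @slot boundaryFlags Named logical; `TRUE` where a non-negativity bound is
#'   active.
#' @slot details List of fit metadata (condition labels, MSE, convergence
#'   info).
#' @export MLQFit
#' @exportClass MLQFit
MLQFit <- setClass("MLQFit",
  representation(
    estimates = "numeric",
    sigmas = "numeric",
    covariance = "matrix",
    objective = "numeric",
    nPoints = "integer",
    boundaryFlags = "logical",
    details = "list"
  )
)

setValidity("MLQFit", function(object) {
  msg <- character()
  p <- length(object@estimates)
  if (is.null(names(object@estimates)))
    msg <- c(msg, "'estimates' must be named")
  if (length(object@sigmas) != p || length(object@boundaryFlags) != p)
    msg <- c(msg, "'sigmas' and 'boundaryFlags' must match 'estimates'")
  if (any(object@sigmas < 0, na.rm = TRUE))
    msg <- c(msg, "'sigmas' must be >= 0")
  if (!all(dim(object@covariance) == c(p, p)))
    msg <- c(msg, "'covariance' must be p x p")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("estimates", "MLQFit", function(object) object@estimates)

#' @rdname accessors
#' @export
setMethod("sigmas", "MLQFit", function(object) object@sigmas)

#' @rdname accessors
#' @export
setMethod("covariance", "MLQFit", function(object) object@covariance)

#' @rdname accessors
#' @export
setMethod("boundaryFlags", "MLQFit", function(object) object@boundaryFlags)

setMethod("show", "MLQFit", function(object) {
  cat("MLQFit over", object@nPoints, "points; weighted RSS =",
      format(object@objective, digits = 4), "\n")
  est <- object@estimates
  for (i in seq_along(est)) {
    flag <- if (object@boundaryFlags[i]) " [at bound]" else ""
    cat(sprintf("  %-8s %10.5g +/- %-10.4g%s\n",
                names(est)[i], est[i], object@sigmas[i], flag))
  }
})

## ---- DoseComponentField -----------------------------------------------------

#' Four-component 3D dose(-rate) field
#'
#' Co-registered 3D grids of the four BNCT dose components as produced by
#' treatment-planning transport calculations: boron dose per ppm of boron-10
#' concentration, thermal-neutron (capture) dose, fast-neutron (recoil)
#' dose, and photon dose. In `"rate"` mode values are Gy/min (boron:
#' Gy/min/ppm) and are multiplied by an irradiation time and, for boron, the
#' ROI boron concentration when converted; in `"absolute"` mode they are Gy
#' (boron: Gy/ppm). The thermal and fast neutron grids are summed into the
#' model's single neutron component when survival-based conversion is
#' applied.
#'
#' @slot boronPerPpm,thermalNeutron,fastNeutron,photon 3D numeric arrays of
#'   a common dim.
#' @slot spacing Voxel spacing per axis (mm).
#' @slot origin Coordinate of the first voxel centre per axis (mm).
#' @slot unitsMode `"rate"` or `"absolute"`.
#'
#' @param boronPerPpm,thermalNeutron,fastNeutron,photon,spacing,origin,unitsMode
#'   See slots.
#' @export DoseComponentField
#' @exportClass DoseComponentField
DoseComponentField <- setClass("DoseComponentField",
  representation(
    boronPerPpm = "array",
    thermalNeutron = "array",
    fastNeutron = "array",
    photon = "array",
    spacing = "numeric",
    origin = "numeric",
    unitsMode = "character"
  ),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), unitsMode = "rate")
)

setValidity("DoseComponentField", function(object) {
  msg <- character()
  d <- dim(object@boronPerPpm)
  if (length(d) != 3L) msg <- c(msg, "grids must be 3D arrays")
  for (s in c("thermalNeutron", "fastNeutron", "photon"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("'%s' grid dim differs from boron grid", s))
  vals <- c(object@boronPerPpm, object@thermalNeutron, object@fastNeutron,
            object@photon)
  if (anyNA(vals) || any(vals < 0))
    msg <- c(msg, "all grid values must be finite and >= 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "'origin' must have three values")
  if (!object@unitsMode %in% c("rate", "absolute"))
    msg <- c(msg, "'unitsMode' must be \"rate\" or \"absolute\"")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("gridSpacing", "DoseComponentField", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "DoseComponentField", function(object) object@origin)

#' @rdname accessors
#' @param component One of `"boronPerPpm"`, `"thermalNeutron"`,
#'   `"fastNeutron"`, `"photon"`.
#' @export
setMethod("componentGrid", "DoseComponentField", function(object, component) {
  component <- match.arg(component,
    c("boronPerPpm", "thermalNeutron", "fastNeutron", "photon"))
  slot(object, component)
})

setMethod("show", "DoseComponentField", function(object) {
  d <- dim(object@boronPerPpm)
  cat(sprintf("DoseComponentField: %d x %d x %d voxels, %s mode\n",
              d[1], d[2], d[3], object@unitsMode))
  cat("  spacing (mm):", paste(object@spacing, collapse = " x "), "\n")
})

## ---- ROIMask ----------------------------------------------------------------

#' Region-of-interest mask
#'
#' A boolean voxel mask co-registered with a [DoseComponentField], carrying
#' the ROI name and its boron-10 concentration (ppm) used to scale the
#' per-ppm boron dose grid.
#'
#' @slot mask 3D logical array.
#' @slot name ROI label (e.g. `"GTV"`, `"brain"`).
#' @slot boronConcentration Boron concentration in the ROI (ppm, >= 0).
#'
#' @param mask,name,boronConcentration See slots.
#' @export ROIMask
#' @exportClass ROIMask
ROIMask <- setClass("ROIMask",
  representation(mask = "array", name = "character",
                 boronConcentration = "numeric"),
  prototype(name = "ROI", boronConcentration = 0)
)

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a 3D logical array")
  else if (!any(object@mask))
    msg <- c(msg, "'mask' must contain at least one voxel")
  if (length(object@boronConcentration) != 1L ||
      is.na(object@boronConcentration) || object@boronConcentration < 0)
    msg <- c(msg, "'boronConcentration' must be a scalar >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("maskArray", "ROIMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("boronConcentration", "ROIMask",
          function(object) object@boronConcentration)

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask '%s': %d voxels, %g ppm boron\n",
              object@name, sum(object@mask), object@boronConcentration))
})

## ---- DVHCurve & DoseSummary -------------------------------------------------

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of one ROI: `volumeFraction[k]` is the fraction of the ROI
#' volume receiving at least `doseEdges[k]` Gy-equivalent. The curve starts
#' at 1 (every voxel receives at least 0) and ends at 0.
#'
#' @slot doseEdges Dose bin edges (Gy-equivalent), increasing.
#' @slot volumeFraction Cumulative volume fraction per edge, non-increasing.
#' @slot roiName ROI label.
#' @slot model Photon-equivalent model used (`"isoeffective"`,
#'   `"rbe_weighted"` or `"none"`).
#'
#' @param doseEdges,volumeFraction,roiName,model See slots.
#' @export DVHCurve
#' @exportClass DVHCurve
DVHCurve <- setClass("DVHCurve",
  representation(doseEdges = "numeric", volumeFraction = "numeric",
                 roiName = "character", model = "character"),
  prototype(roiName = "ROI", model = "none")
)

setValidity("DVHCurve", function(object) {
  msg <- character()
  n <- length(object@doseEdges)
  if (length(object@volumeFraction) != n)
    msg <- c(msg, "'doseEdges' and 'volumeFraction' must have equal length")
  if (is.unsorted(object@doseEdges))
    msg <- c(msg, "'doseEdges' must be increasing")
  if (any(diff(object@volumeFraction) > 1e-12))
    msg <- c(msg, "'volumeFraction' must be non-increasing")
  if (n > 0 && (abs(object@volumeFraction[1] - 1) > 1e-12 ||
                abs(object@volumeFraction[n]) > 1e-12))
    msg <- c(msg, "'volumeFraction' must start at 1 and end at 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve '%s' (%s model): %d edges up to %.3g Gy-eq\n",
              object@roiName, object@model, length(object@doseEdges),
              max(object@doseEdges)))
})

#' Dose summary statistics of an ROI
#'
#' Maximum, mean and minimum photon-equivalent dose over the voxels of an
#' ROI, tagged with the conversion model and the parameter provenance.
#'
#' @slot dMax,dMean,dMin Gy-equivalent summaries (`dMin <= dMean <= dMax`).
#' @slot model `"isoeffective"`, `"rbe_weighted"` or `"none"`.
#' @slot parameterLabel Provenance of the parameters or weights used.
#' @slot roiName ROI label.
#'
#' @param dMax,dMean,dMin,model,parameterLabel,roiName See slots.
#' @export DoseSummary
#' @exportClass DoseSummary
DoseSummary <- setClass("DoseSummary",
  representation(dMax = "numeric", dMean = "numeric", dMin = "numeric",
                 model = "character", parameterLabel = "character",
                 roiName = "character"),
  prototype(model = "none", parameterLabel = "", roiName = "ROI")
)

setValidity("DoseSummary", function(object) {
  if (length(object@dMax) != 1L || length(object@dMean) != 1L ||
      length(object@dMin) != 1L)
    return("'dMax', 'dMean', 'dMin' must be scalars")
  if (!(object@dMin <= object@dMean + 1e-12 &&
        object@dMean <= object@dMax + 1e-12))
    "'dMin' <= 'dMean' <= 'dMax' must hold"
  else TRUE
})

setMethod("show", "DoseSummary", function(object) {
  cat(sprintf("DoseSummary '%s' (%s, %s): Dmax %.1f / Dmean %.1f / Dmin %.1f\n",
              object@roiName, object@model, object@parameterLabel,
              object@dMax, object@dMean, object@dMin))
})

## ---- AssayDesign & PhantomSpec ---------------------------------------------

#' Clonogenic assay design
#'
#' Design of a synthetic clonogenic assay: the dose points (one
#' [MixedFieldDose] row each, via its component columns), the per-point
#' protocol duration, seeding and plating parameters, replicate count and
#' the relative uncertainty of the boron dose (dominated in practice by the
#' boron-concentration measurement).
#'
#' @slot condition `"reference_photon"`, `"beam_only"` or `"bpa_bnct"`.
#' @slot doses data.frame with columns `boron`, `neutron`, `photon` (Gy).
#' @slot durationMin Irradiation time per point (min); scalar or per-point.
#' @slot cellsSeeded Cells seeded per flask; scalar or per-point (labs seed
#'   more cells at higher doses to keep colony counts countable).
#' @slot platingEfficiency Fraction of unirradiated cells forming colonies.
#' @slot replicates Flasks per dose point.
#' @slot boronSigmaRel Relative (Gaussian) uncertainty of the boron dose.
#'
#' @param condition,doses,durationMin,cellsSeeded,platingEfficiency,replicates,boronSigmaRel
#'   See slots.
#' @export AssayDesign
#' @exportClass AssayDesign
AssayDesign <- setClass("AssayDesign",
  representation(
    condition = "character",
    doses = "data.frame",
    durationMin = "numeric",
    cellsSeeded = "numeric",
    platingEfficiency = "numeric",
    replicates = "integer",
    boronSigmaRel = "numeric"
  ),
  prototype(condition = "reference_photon", durationMin = 0,
            cellsSeeded = 1000, platingEfficiency = 0.7, replicates = 3L,
            boronSigmaRel = 0)
)

setValidity("AssayDesign", function(object) {
  msg <- character()
  if (!object@condition %in% c("reference_photon", "beam_only", "bpa_bnct"))
    msg <- c(msg, "unknown 'condition'")
  if (!all(c("boron", "neutron", "photon") %in% names(object@doses)))
    msg <- c(msg, "'doses' needs columns boron, neutron, photon")
  if (object@platingEfficiency <= 0 || object@platingEfficiency > 1)
    msg <- c(msg, "'platingEfficiency' must be in (0, 1]")
  if (any(object@cellsSeeded <= 0)) msg <- c(msg, "'cellsSeeded' must be > 0")
  if (object@replicates < 1L) msg <- c(msg, "'replicates' must be >= 1")
  if (object@boronSigmaRel < 0) msg <- c(msg, "'boronSigmaRel' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom specification
#'
#' A rectangular water-equivalent block with a spherical tumor, irradiated
#' along one axis: each dose component's rate decays exponentially with its
#' attenuation length from a surface value. This is deliberately the
#' simplest geometry that exercises ROI-dependent boron scaling and DVH
#' shape; it makes no claim of matching any patient case.
#'
#' @slot shape Voxels per axis (3 integers).
#' @slot spacing Voxel spacing (mm per axis).
#' @slot beamAxis Axis index (1-3) along which the beam attenuates.
#' @slot attenuationLengths Attenuation length (cm) per component, named
#'   `boronPerPpm`, `thermalNeutron`, `fastNeutron`, `photon`.
#' @slot surfaceDoseRates Surface dose rate (Gy/min; boron Gy/min/ppm) per
#'   component, same names.
#' @slot tumorCenter Tumor sphere centre (voxel coordinates).
#' @slot tumorRadius Tumor sphere radius (mm).
#' @slot boronTumorPpm,boronBrainPpm Boron concentrations (ppm).
#'
#' @param shape,spacing,beamAxis,attenuationLengths,surfaceDoseRates,tumorCenter,tumorRadius,boronTumorPpm,boronBrainPpm
#'   See slots.
#' @export PhantomSpec
#' @exportClass PhantomSpec
PhantomSpec <- setClass("PhantomSpec",
  representation(
    shape = "integer",
    spacing = "numeric",
    beamAxis = "integer",
    attenuationLengths = "numeric",
    surfaceDoseRates = "numeric",
    tumorCenter = "numeric",
    tumorRadius = "numeric",
    boronTumorPpm = "numeric",
    boronBrainPpm = "numeric"
  ),
  prototype(
    shape = c(24L, 24L, 40L),
    spacing = c(5, 5, 5),
    beamAxis = 3L,
    attenuationLengths = c(boronPerPpm = 3.5, thermalNeutron = 3.5,
                           fastNeutron = 2.0, photon = 10.0),
    surfaceDoseRates = c(boronPerPpm = 0.02, thermalNeutron = 0.02,
                         fastNeutron = 0.01, photon = 0.02),
    tumorCenter = c(12, 12, 4),
    tumorRadius = 15,
    boronTumorPpm = 40,
    boronBrainPpm = 13.6
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "'shape' must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive values")
  if (!object@beamAxis %in% 1:3) msg <- c(msg, "'beamAxis' must be 1, 2 or 3")
  nm <- c("boronPerPpm", "thermalNeutron", "fastNeutron", "photon")
  if (!all(nm %in% names(object@attenuationLengths)) ||
      any(object@attenuationLengths <= 0))
    msg <- c(msg, "'attenuationLengths' must be positive and named per component")
  if (!all(nm %in% names(object@surfaceDoseRates)) ||
      any(object@surfaceDoseRates < 0))
    msg <- c(msg, "'surfaceDoseRates' must be >= 0 and named per component")
  if (object@tumorRadius <= 0) msg <- c(msg, "'tumorRadius' must be > 0")
  if (length(msg)) return(msg)
  # tumor sphere must fit inside the phantom
  ctr <- (object@tumorCenter - 0.5) * object@spacing
  ext <- object@shape * object@spacing
  if (any(ctr - object@tumorRadius < 0) || any(ctr + object@tumorRadius > ext))
    return("tumor sphere extends outside the phantom")
  TRUE
})
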