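#' @include dosimetry.R
NULL

# Assemble per-voxel component doses (Gy) for the ROI voxels of a field.
# Boron grid is per-ppm and scaled by the ROI concentration; the two
# neutron grids are summed into the model's single neutron component; in
# rate mode everything is multiplied by the irradiation time.
assembleComponentDoses <- function(field, roi, irradiationTime) {
  sel <- roi@mask
  scale <- if (field@unitsMode == "rate") {
    if (is.null(irradiationTime) || is.na(irradiationTime) ||
        irradiationTime <= 0)
      stop("rate-mode fields need a positive 'irradiationTime'")
    irradiationTime
  } else 1
  list(
    boron = field@boronPerPpm[sel] * roi@boronConcentration * scale,
    neutron = (field@thermalNeutron[sel] + field@fastNeutron[sel]) * scale,
    photon = field@photon[sel] * scale
  )
}

#' Convert a dose-component field to photon-equivalent units
#'
#' Voxelwise conversion of the four co-registered component grids inside an
#' ROI into a photon-equivalent dose grid, with either the photon
#' isoeffective model or the fixed-factor RBE-weighted model. Per voxel, the
#' component doses are assembled (boron per-ppm grid scaled by the ROI boron
#' concentration; thermal and fast neutron grids summed; rates multiplied by
#' the irradiation time) and the scalar model is applied with the
#' irradiation time as the mixed-field protraction duration. Voxels outside
#' the ROI are `NA`.
#'
#' @param field [DoseComponentField].
#' @param roi [ROIMask] co-registered with `field`.
#' @param model `"isoeffective"` or `"rbe_weighted"`.
#' @param params [RadiobiologicalParameterSet] (isoeffective model).
#' @param weights [RBEWeights] (RBE-weighted model).
#' @param irradiationTime Minutes; required in rate mode, also used as the
#'   mixed-field delivery time for the isoeffective G factors.
#' @param referenceMode,referenceDoseRate Passed to [isoeffectiveDose()].
#' @return 3D array of Gy-equivalent values (`NA` outside the ROI).
#' @examples
#' ph <- generatePhantomField(PhantomSpec(), seed = 1)
#' eq <- convertField(ph$field, ph$rois$tumor, "isoeffective",
#'                    params = gbmParameters(), irradiationTime = 30)
#' @export
convertField <- function(field, roi, model = c("isoeffective", "rbe_weighted"),
                         params = NULL, weights = NULL,
                         irradiationTime = NULL,
                         referenceMode = "acute", referenceDoseRate = 1) {
  model <- match.arg(model)
  stopifnot(is(field, "DoseComponentField"), is(roi, "ROIMask"))
  if (!identical(dim(roi@mask), dim(field@photon)))
    stop("registration error: ROI mask and dose grids differ in shape")
  if (field@unitsMode == "rate" && model == "isoeffective" &&
      roi@boronConcentration == 0 && any(field@boronPerPpm > 0))
    warning("ROI boron concentration is 0: boron grid contributes nothing")
  comp <- assembleComponentDoses(field, roi, irradiationTime)
  d <- MixedFieldDose(comp$boron, comp$neutron, comp$photon)
  vals <- if (model == "isoeffective") {
    if (is.null(params)) stop("isoeffective model needs 'params'")
    theta <- if (is.null(irradiationTime)) 0 else irradiationTime
    isoeffectiveDose(d, params, protocol = theta,
                     referenceMode = referenceMode,
                     referenceDoseRate = referenceDoseRate)
  } else {
    if (is.null(weights)) stop("rbe_weighted model needs 'weights'")
    rbeWeightedDose(d, weights)
  }
  out <- array(NA_real_, dim(field@photon))
  out[roi@mask] <- vals
  out
}

#' Cumulative dose-volume histogram of an ROI
#'
#' Cumulative DVH over the ROI voxels of a photon-equivalent grid:
#' `volumeFraction[k]` is the fraction of ROI voxels with dose `>=`
#' `doseEdges[k]`. Edges are uniform from 0 to just above the ROI maximum,
#' so the curve starts at 1 and ends at 0.
#'
#' @param equivalentGrid 3D array (e.g. from [convertField()]).
#' @param roi [ROIMask].
#' @param nBins Number of bins (default 256).
#' @param model Model label stored on the curve.
#' @return A [DVHCurve].
#' @export
computeDVH <- function(equivalentGrid, roi, nBins = 256L, model = "none") {
  stopifnot(is(roi, "ROIMask"))
  if (!identical(dim(roi@mask), dim(equivalentGrid)))
    stop("registration error: grid and ROI mask differ in shape")
  vals <- equivalentGrid[roi@mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("invalid mask: no dose values inside the ROI")
  top <- max(vals)
  upper <- if (top > 0) top * (1 + 1e-9) else 1
  edges <- seq(0, upper, length.out = nBins + 1L)
  vf <- vapply(edges, function(e) mean(vals >= e), numeric(1))
  DVHCurve(doseEdges = edges, volumeFraction = vf, roiName = roi@name,
           model = model)
}

#' Dose statistics of an ROI
#'
#' Maximum, mean and minimum Gy-equivalent dose over the ROI voxels.
#'
#' @param equivalentGrid 3D array.
#' @param roi [ROIMask].
#' @param model,parameterLabel Provenance stored on the summary.
#' @return A [DoseSummary].
#' @export
doseStatistics <- function(equivalentGrid, roi, model = "none",
                           parameterLabel = "") {
  stopifnot(is(roi, "ROIMask"))
  if (!identical(dim(roi@mask), dim(equivalentGrid)))
    stop("registration error: grid and ROI mask differ in shape")
  vals <- equivalentGrid[roi@mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("invalid mask: no dose values inside the ROI")
  DoseSummary(dMax = max(vals), dMean = mean(vals), dMin = min(vals),
              model = model, parameterLabel = parameterLabel,
              roiName = roi@name)
}

#' Irradiation time meeting a normal-tissue DVH prescription
#'
#' Largest irradiation time such that the RBE-weighted DVH of a normal
#' tissue ROI satisfies "no more than `volumeFraction` of the volume
#' receives more than `limit` Gy(RBE)". Because the RBE-weighted dose is
#' linear in time for a rate-mode field, the answer is closed-form: the
#' limit divided by the per-minute weighted dose rate at the
#' `volumeFraction` DVH point (the `1 - volumeFraction` quantile of the
#' voxel rate distribution; the median for the usual 50% prescription).
#'
#' @param field Rate-mode [DoseComponentField].
#' @param brainRoi [ROIMask] of the normal tissue, with its boron
#'   concentration.
#' @param weights [RBEWeights] used for the prescription (fixed factors, as
#'   in clinical practice).
#' @param limit Prescription dose limit, Gy(RBE) (default 2.5).
#' @param volumeFraction Volume fraction of the prescription (default 0.5).
#' @return Irradiation time in minutes.
#' @export
scaleTimeToPrescription <- function(field, brainRoi, weights = RBEWeights(),
                                    limit = 2.5, volumeFraction = 0.5) {
  stopifnot(is(field, "DoseComponentField"), is(brainRoi, "ROIMask"))
  if (field@unitsMode != "rate")
    stop("prescription scaling needs a rate-mode field")
  if (limit < 0) stop("'limit' must be >= 0")
  if (volumeFraction <= 0 || volumeFraction >= 1)
    stop("'volumeFraction' must lie in (0, 1)")
  comp <- assembleComponentDoses(field, brainRoi, irradiationTime = 1)
  ratePerMin <- rbeWeightedDose(
    MixedFieldDose(comp$boron, comp$neutron, comp$photon), weights)
  dvhRate <- stats::quantile(ratePerMin, probs = 1 - volumeFraction,
                             names = FALSE, type = 7)
  if (dvhRate <= 0)
    stop("unbounded time: the weighted dose rate at the prescription point is zero")
  limit / dvhRate
}

#' Percentage difference between two dose values
#'
#' Reporting convention for model/parameter-set comparisons:
#' `100 * (reference - other) / reference`, rounded to the nearest integer
#' when `rounded = TRUE` (the convention used for tabulated comparisons;
#' dose summaries themselves are conventionally rounded to 0.1 Gy-eq).
#'
#' @param referenceValue Denominator value (> 0), Gy-equivalent.
#' @param otherValue Comparison value.
#' @param rounded Round to the nearest integer percent (default TRUE).
#' @return Percentage (numeric).
#' @examples
#' percentDifference(35.2, 25.5)   # 28
#' @export
percentDifference <- function(referenceValue, otherValue, rounded = TRUE) {
  if (anyNA(referenceValue) || any(referenceValue <= 0))
    stop("undefined difference: 'referenceValue' must be > 0")
  pct <- 100 * (referenceValue - otherValue) / referenceValue
  if (rounded) round(pct) else pct
}

#' Differential DVH from a cumulative curve
#'
#' Volume fraction per dose bin, derived from the cumulative curve by
#' differencing: bin k spans `doseEdges[k]` to `doseEdges[k+1]`.
#'
#' @param dvh A [DVHCurve].
#' @return data.frame with `doseLow`, `doseHigh`, `volumeFraction`.
#' @export
differentialDVH <- function(dvh) {
  stopifnot(is(dvh, "DVHCurve"))
  n <- length(dvh@doseEdges)
  data.frame(doseLow = dvh@doseEdges[-n], doseHigh = dvh@doseEdges[-1],
             volumeFraction = -diff(dvh@volumeFraction))
}

#' Dose level at a DVH volume fraction
#'
#' The dose D(v) received by at least the fraction `v` of the ROI volume,
#' linearly interpolated on the cumulative curve (e.g. `dvhDoseAt(dvh, 0.5)`
#' is the median DVH dose used in prescriptions).
#'
#' @param dvh A [DVHCurve].
#' @param volumeFraction Fraction(s) in (0, 1).
#' @return Dose (Gy-equivalent).
#' @export
dvhDoseAt <- function(dvh, volumeFraction) {
  stopifnot(is(dvh, "DVHCurve"))
  if (any(volumeFraction <= 0 | volumeFraction >= 1))
    stop("'volumeFraction' must lie in (0, 1)")
  # volumeFraction is non-increasing in dose; invert by interpolation
  stats::approx(x = rev(dvh@volumeFraction), y = rev(dvh@doseEdges),
                xout = volumeFraction, ties = "ordered", rule = 2)$y
}
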