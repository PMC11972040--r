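#' @include synthetic-data.R
NULL

#' Read / write clonogenic survival tables
#'
#' Delimited-text (CSV) survival tables with one row per dose point. Columns:
#' `condition` (`reference_photon`, `beam_only`, `bpa_bnct`), `d_boron`,
#' `d_neutron`, `d_photon` (Gy), `surviving_fraction`, `sf_sigma`,
#' `duration_min`, and optionally `d_boron_sigma` and bookkeeping columns.
#'
#' @param path File path.
#' @param points data.frame to write.
#' @return `readSurvivalTable()` returns the validated data.frame.
#' @export
readSurvivalTable <- function(path) {
  checkSurvivalTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readSurvivalTable
#' @export
writeSurvivalTable <- function(points, path) {
  utils::write.csv(checkSurvivalTable(points), path, row.names = FALSE)
  invisible(path)
}

#' Read a foci-decay time series
#'
#' CSV with columns `time` (min), `intensity` (normalized), and optionally
#' `sigma`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
readFociSeries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "intensity") %in% names(d)))
    stop("foci series needs columns 'time' and 'intensity'")
  d
}

#' Write a fit result to JSON
#'
#' Serializes an [MLQFit] (estimates, 68% half-widths, covariance,
#' objective, bound flags) together with provenance metadata.
#'
#' @param fit [MLQFit].
#' @param path Output path.
#' @param provenance Optional named list recorded verbatim.
#' @return The path, invisibly.
#' @export
writeFitResult <- function(fit, path, provenance = list()) {
  stopifnot(is(fit, "MLQFit"))
  obj <- list(
    estimates = as.list(fit@estimates),
    sigma68 = as.list(fit@sigmas),
    covariance = unname(apply(fit@covariance, 1, as.list)),
    objective = fit@objective,
    n_points = fit@nPoints,
    at_bound = as.list(fit@boundaryFlags),
    mse = fit@details$mse,
    model = fit@details$model,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# ---- parameter sets ---------------------------------------------------------

paramSetToList <- function(params) {
  comp <- function(p) list(alpha = p@alpha, beta = p@beta,
                           let_class = p@letClass)
  list(
    label = params@label,
    photon = comp(params@photon),
    neutron = comp(params@neutron),
    boron = comp(params@boron),
    kinetics = list(
      t0_fast = params@kinetics@t0Fast,
      t0_slow = params@kinetics@t0Slow,
      frac_fast_low_let = params@kinetics@fracFastLowLET,
      frac_fast_high_let = params@kinetics@fracFastHighLET
    )
  )
}

paramSetFromList <- function(x) {
  comp <- function(e) LQParameters(e$alpha, e$beta, e$let_class)
  RadiobiologicalParameterSet(
    photon = comp(x$photon), neutron = comp(x$neutron),
    boron = comp(x$boron),
    kinetics = RepairKinetics(
      t0Fast = x$kinetics$t0_fast, t0Slow = x$kinetics$t0_slow,
      fracFastLowLET = x$kinetics$frac_fast_low_let,
      fracFastHighLET = x$kinetics$frac_fast_high_let),
    label = x$label %||% "unlabelled")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write radiobiological parameter sets
#'
#' [RadiobiologicalParameterSet] serialization as JSON or YAML (chosen by
#' file extension), carrying the per-component alpha/beta pairs, the repair
#' kinetics and the provenance label. Round-trip safe.
#'
#' @param params [RadiobiologicalParameterSet].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `readParameterSet()` returns the object; writers return the path
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeParameterSet(gbmParameters(), f)
#' readParameterSet(f)
#' @export
writeParameterSet <- function(params, path) {
  stopifnot(is(params, "RadiobiologicalParameterSet"))
  x <- paramSetToList(params)
  if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname writeParameterSet
#' @export
readParameterSet <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  paramSetFromList(x)
}

#' Read / write RBE weight sets
#'
#' [RBEWeights] serialization as JSON or YAML.
#'
#' @param weights [RBEWeights].
#' @param path File path.
#' @export
writeRBEWeights <- function(weights, path) {
  stopifnot(is(weights, "RBEWeights"))
  x <- list(label = weights@label, w_boron = weights@boron,
            w_neutron = weights@neutron, w_photon = weights@photon)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname writeRBEWeights
#' @export
readRBEWeights <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  RBEWeights(boron = x$w_boron, neutron = x$w_neutron,
             photon = x$w_photon, label = x$label %||% "unlabelled")
}

# ---- volumetric grids (NIfTI) ----------------------------------------------

#' Write / read a dose-component field as NIfTI volumes
#'
#' One NIfTI file per component (suffixes `_boron_per_ppm`,
#' `_thermal_neutron`, `_fast_neutron`, `_photon`) sharing the affine built
#' from the grid spacing and origin, plus a small JSON sidecar
#' (`<prefix>.json`) with the units mode.
#'
#' @param field [DoseComponentField].
#' @param prefix Path prefix (files are `<prefix>_<component>.nii.gz`).
#' @return `readDoseField()` returns the [DoseComponentField]; the writer
#'   returns the prefix invisibly.
#' @export
writeDoseField <- function(field, prefix) {
  stopifnot(is(field, "DoseComponentField"))
  comps <- c(boron_per_ppm = "boronPerPpm", thermal_neutron = "thermalNeutron",
             fast_neutron = "fastNeutron", photon = "photon")
  for (i in seq_along(comps)) {
    img <- RNifti::asNifti(slot(field, comps[[i]]),
                           pixdim = field@spacing)
    RNifti::writeNifti(img, paste0(prefix, "_", names(comps)[i], ".nii.gz"))
  }
  jsonlite::write_json(
    list(units_mode = field@unitsMode, spacing = field@spacing,
         origin = field@origin),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeDoseField
#' @export
readDoseField <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(suffix) {
    img <- RNifti::readNifti(paste0(prefix, "_", suffix, ".nii.gz"))
    array(as.numeric(img), dim(img))
  }
  DoseComponentField(
    boronPerPpm = rd("boron_per_ppm"), thermalNeutron = rd("thermal_neutron"),
    fastNeutron = rd("fast_neutron"), photon = rd("photon"),
    spacing = as.numeric(meta$spacing), origin = as.numeric(meta$origin),
    unitsMode = meta$units_mode)
}

#' Write / read an ROI mask as NIfTI
#'
#' The mask is stored as 0/1 integers; the name and boron concentration go
#' into a JSON sidecar.
#'
#' @param roi [ROIMask].
#' @param prefix Path prefix.
#' @export
writeROIMask <- function(roi, prefix) {
  stopifnot(is(roi, "ROIMask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(roi@mask),
                                           dim(roi@mask))),
                     paste0(prefix, ".nii.gz"))
  jsonlite::write_json(
    list(name = roi@name, boron_concentration_ppm = roi@boronConcentration),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeROIMask
#' @export
readROIMask <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  ROIMask(mask = array(as.numeric(img) > 0.5, dim(img)),
          name = meta$name, boronConcentration = meta$boron_concentration_ppm)
}

#' Export a DVH curve as CSV
#'
#' @param dvh [DVHCurve].
#' @param path Output path.
#' @export
writeDVH <- function(dvh, path) {
  stopifnot(is(dvh, "DVHCurve"))
  utils::write.csv(
    data.frame(dose_gy_eq = dvh@doseEdges,
               volume_fraction = dvh@volumeFraction),
    path, row.names = FALSE)
  invisible(path)
}
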