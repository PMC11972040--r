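#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the radiobiological value classes.
#' Accessors are preferred over direct slot access (`@`), which is not part
#' of the public interface.
#'
#' @param object An object of one of the package's S4 classes.
#' @param x An object of one of the package's S4 classes.
#' @param ... Passed on to methods.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alpha", function(object) standardGeneric("alpha"))

#' @rdname accessors
#' @export
setGeneric("beta", function(object) standardGeneric("beta"))

#' @rdname accessors
#' @export
setGeneric("letClass", function(object) standardGeneric("letClass"))

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("doseRate", function(object) standardGeneric("doseRate"))

#' @rdname accessors
#' @export
setGeneric("doseComponents", function(object) standardGeneric("doseComponents"))

#' @rdname accessors
#' @export
setGeneric("totalDose", function(object) standardGeneric("totalDose"))

#' @rdname accessors
#' @export
setGeneric("kinetics", function(object) standardGeneric("kinetics"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))

#' @rdname accessors
#' @export
setGeneric("covariance", function(object) standardGeneric("covariance"))

#' @rdname accessors
#' @export
setGeneric("boundaryFlags", function(object) standardGeneric("boundaryFlags"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("componentGrid", function(object, component) standardGeneric("componentGrid"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("boronConcentration", function(object) standardGeneric("boronConcentration"))

#' Confidence intervals for a model fit
#'
#' @param fit An [MLQFit] object.
#' @param level Two-sided confidence level as a fraction (default 0.68,
#'   i.e. "one sigma" intervals as conventionally reported for
#'   radiobiological parameters).
#' @param ... Passed on to methods.
#' @export
setGeneric("confidenceIntervals", function(fit, level = 0.68, ...)
  standardGeneric("confidenceIntervals"))
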