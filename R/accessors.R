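#' Accessors for IVIM objects
#'
#' `dCoef()`, `dStar()` and `perfFraction()` extract the molecular-diffusion
#' coefficient D, the pseudo-diffusion coefficient D* and the
#' pseudo-diffusion fraction f. `perfFlux()` returns the derived
#' pseudo-diffusion flux f*D* (mm^2/s); it is always recomputed from the two
#' stored parameters.
#'
#' @param object an \linkS4class{IVIMParams} or \linkS4class{FitResult}.
#' @return a single numeric value.
#' @examples
#' p <- IVIMParams(1e-3, 30e-3, 0.12)
#' c(dCoef(p), dStar(p), perfFraction(p), perfFlux(p))
#' @name ivim-accessors
NULL

#' @rdname ivim-accessors
#' @export
setGeneric("dCoef", function(object) standardGeneric("dCoef"))
#' @rdname ivim-accessors
#' @export
setGeneric("dStar", function(object) standardGeneric("dStar"))
#' @rdname ivim-accessors
#' @export
setGeneric("perfFraction", function(object) standardGeneric("perfFraction"))
#' @rdname ivim-accessors
#' @export
setGeneric("perfFlux", function(object) standardGeneric("perfFlux"))

#' @rdname ivim-accessors
#' @export
setMethod("dCoef", "IVIMParams", function(object) object@D)
#' @rdname ivim-accessors
#' @export
setMethod("dStar", "IVIMParams", function(object) object@Dstar)
#' @rdname ivim-accessors
#' @export
setMethod("perfFraction", "IVIMParams", function(object) object@f)
#' @rdname ivim-accessors
#' @export
setMethod("perfFlux", "IVIMParams", function(object) object@f * object@Dstar)

#' @rdname ivim-accessors
#' @export
setMethod("dCoef", "FitResult", function(object) object@params@D)
#' @rdname ivim-accessors
#' @export
setMethod("dStar", "FitResult", function(object) object@params@Dstar)
#' @rdname ivim-accessors
#' @export
setMethod("perfFraction", "FitResult", function(object) object@params@f)
#' @rdname ivim-accessors
#' @export
setMethod("perfFlux", "FitResult", function(object) perfFlux(object@params))

#' Accessors for signal curves and fit results
#'
#' @param object a \linkS4class{SignalCurve}, \linkS4class{DiffusionVolume},
#'   \linkS4class{PseudoDiffusionCurve} or \linkS4class{FitResult}.
#' @return `bValues()` the b-values; `signalIntensities()` the intensities;
#'   `s0()` the measured S(0); `fittedParams()` the
#'   \linkS4class{IVIMParams}; `fitMethod()` the method name;
#'   `isConverged()` the convergence flag; `intermediates()` the named list
#'   of stage outputs.
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname curve-accessors
#' @export
setGeneric("signalIntensities",
           function(object) standardGeneric("signalIntensities"))
#' @rdname curve-accessors
#' @export
setGeneric("s0", function(object) standardGeneric("s0"))
#' @rdname curve-accessors
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))
#' @rdname curve-accessors
#' @export
setGeneric("fitMethod", function(object) standardGeneric("fitMethod"))
#' @rdname curve-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname curve-accessors
#' @export
setGeneric("intermediates", function(object) standardGeneric("intermediates"))

#' @rdname curve-accessors
#' @export
setMethod("bValues", "SignalCurve", function(object) object@bvalues)
#' @rdname curve-accessors
#' @export
setMethod("signalIntensities", "SignalCurve", function(object) object@signal)
#' @rdname curve-accessors
#' @export
setMethod("s0", "SignalCurve", function(object) object@signal[1])
#' @rdname curve-accessors
#' @export
setMethod("bValues", "DiffusionVolume", function(object) object@bvalues)
#' @rdname curve-accessors
#' @export
setMethod("bValues", "PseudoDiffusionCurve", function(object) object@bvalues)

#' @rdname curve-accessors
#' @export
setMethod("fittedParams", "FitResult", function(object) object@params)
#' @rdname curve-accessors
#' @export
setMethod("fitMethod", "FitResult", function(object) object@method)
#' @rdname curve-accessors
#' @export
setMethod("isConverged", "FitResult", function(object) object@converged)
#' @rdname curve-accessors
#' @export
setMethod("intermediates", "FitResult", function(object) object@intermediates)

#' @rdname curve-accessors
#' @export
ftilde <- function(object) {
  stopifnot(is(object, "PseudoDiffusionCurve"))
  object@ftilde
}

setMethod("show", "IVIMParams", function(object) {
  cat(sprintf(
    "IVIMParams: D = %.4g mm^2/s, D* = %.4g mm^2/s, f = %.4g (f*D* = %.4g)\n",
    object@D, object@Dstar, object@f, object@f * object@Dstar))
})

setMethod("show", "SignalCurve", function(object) {
  cat(sprintf("SignalCurve: %d b-values in [0, %g] s/mm^2, S(0) = %.4g\n",
              length(object@bvalues), max(object@bvalues), object@signal[1]))
})

setMethod("show", "MonoExpFit", function(object) {
  cat(sprintf(
    "MonoExpFit: D~ = %.4g mm^2/s, S_int = %.4g (b_t = %g, %d points)\n",
    object@Dtilde, object@Sint, object@bt, object@nPoints))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]%s\n", object@method,
              if (object@converged) "" else " (not converged)"))
  show(object@params)
  if (nzchar(object@message)) cat("  note: ", object@message, "\n", sep = "")
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0(
    "SimulationSpec: D = %.3g mm^2/s; %d f x %d D* cells; %d b-values; ",
    "SNR {%s}; %d reps; seed %d\n"),
    object@D, length(object@fGrid), length(object@DstarGrid),
    length(object@bvalues), paste(object@snrLevels, collapse = ", "),
    object@nReps, object@seed))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s volume, %d b-values, SNR %g, seed %d\n",
    paste(object@shape, collapse = " x "), length(object@bvalues),
    object@snr, object@seed))
})

setMethod("show", "DiffusionVolume", function(object) {
  cat(sprintf("DiffusionVolume: %s voxels x %d b-values (max b = %g s/mm^2)\n",
              paste(dim(object@data)[1:3], collapse = " x "),
              length(object@bvalues), max(object@bvalues)))
})

setMethod("show", "ParameterMaps", function(object) {
  n <- sum(!is.na(object@D))
  cat(sprintf(
    "ParameterMaps [%s]: %s voxels, %d fitted (%.1f%% converged)\n",
    object@method, paste(dim(object@D), collapse = " x "), n,
    if (n) 100 * sum(object@converged, na.rm = TRUE) / n else 0))
})
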