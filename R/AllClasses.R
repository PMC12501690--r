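#' @import methods
NULL

#' IVIM parameter triple
#'
#' Container for the intravoxel incoherent motion (IVIM) parameters of one
#' voxel or tissue: the molecular-diffusion coefficient `D` (mm^2/s), the
#' pseudo-diffusion coefficient `Dstar` (mm^2/s) attributed to capillary
#' microcirculation, and the pseudo-diffusion (perfusion) fraction `f`.
#' The pseudo-diffusion flux f*D* is always derived via [perfFlux()] and
#' never stored.
#'
#' @slot D molecular-diffusion coefficient, mm^2/s, non-negative.
#' @slot Dstar pseudo-diffusion coefficient, mm^2/s, non-negative.
#' @slot f pseudo-diffusion fraction in \[0, 1\].
#' @seealso [ivimSignal()], [adcAtOrigin()], [perfFlux()]
#' @export
setClass("IVIMParams",
  representation(D = "numeric", Dstar = "numeric", f = "numeric"))

setValidity("IVIMParams", function(object) {
  msg <- NULL
  if (length(object@D) != 1L || !is.finite(object@D) || object@D < 0)
    msg <- c(msg, "'D' must be a single finite non-negative number")
  if (length(object@Dstar) != 1L || !is.finite(object@Dstar) || object@Dstar < 0)
    msg <- c(msg, "'Dstar' must be a single finite non-negative number")
  if (length(object@f) != 1L || !is.finite(object@f) ||
      object@f < 0 || object@f > 1)
    msg <- c(msg, "'f' must be a single number in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @param D molecular-diffusion coefficient, mm^2/s.
#' @param Dstar pseudo-diffusion coefficient, mm^2/s.
#' @param f pseudo-diffusion fraction in \[0, 1\].
#' @return `IVIMParams()` returns an \linkS4class{IVIMParams} object.
#' @examples
#' p <- IVIMParams(D = 1e-3, Dstar = 30e-3, f = 0.12)
#' perfFlux(p)
#' @rdname IVIMParams-class
#' @export
IVIMParams <- function(D, Dstar, f) {
  new("IVIMParams", D = as.numeric(D), Dstar = as.numeric(Dstar),
      f = as.numeric(f))
}

#' Diffusion-weighted signal decay curve
#'
#' One measured (or simulated) diffusion decay: b-values in s/mm^2 paired with
#' signal intensities in arbitrary units. b-values are sorted ascending and
#' duplicate b-values are averaged at construction; the first b-value must be
#' 0 and its signal, S(0), must be positive. At least 4 points are required
#' (the minimum for any of the two-stage fitting methods).
#'
#' @slot bvalues strictly increasing b-values, s/mm^2, starting at 0.
#' @slot signal matched signal intensities; `signal[1]` is S(0).
#' @seealso [fitCurve()]
#' @export
setClass("SignalCurve",
  representation(bvalues = "numeric", signal = "numeric"))

setValidity("SignalCurve", function(object) {
  b <- object@bvalues; s <- object@signal
  msg <- NULL
  if (length(b) != length(s))
    msg <- c(msg, "'bvalues' and 'signal' must have equal length")
  if (length(b) < 4L)
    msg <- c(msg, "at least 4 b-values are required")
  if (length(b) && (any(!is.finite(b)) || b[1] != 0 || any(diff(b) <= 0)))
    msg <- c(msg, "'bvalues' must be finite, strictly increasing, starting at 0")
  if (length(s) && any(!is.finite(s)))
    msg <- c(msg, "'signal' must be finite")
  if (length(s) && length(b) == length(s) && b[1] == 0 && s[1] <= 0)
    msg <- c(msg, "S(0) (the signal at b = 0) must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param bvalues b-values, s/mm^2.
#' @param signal signal intensities matched to `bvalues`.
#' @return `SignalCurve()` returns a \linkS4class{SignalCurve}; duplicate
#'   b-values are averaged and points sorted by b.
#' @examples
#' b <- c(0, 50, 100, 200, 500)
#' s <- ivimSignal(IVIMParams(1e-3, 20e-3, 0.1), b)
#' SignalCurve(b, s)
#' @rdname SignalCurve-class
#' @export
SignalCurve <- function(bvalues, signal) {
  bvalues <- as.numeric(bvalues); signal <- as.numeric(signal)
  if (length(bvalues) != length(signal))
    stop("'bvalues' and 'signal' must have equal length")
  if (anyDuplicated(bvalues)) {
    signal <- as.numeric(tapply(signal, bvalues, mean))
    bvalues <- sort(unique(bvalues))
  } else if (is.unsorted(bvalues)) {
    o <- order(bvalues)
    bvalues <- bvalues[o]; signal <- signal[o]
  }
  new("SignalCurve", bvalues = bvalues, signal = signal)
}

#' Mono-exponential tail fit
#'
#' Result of the log-linear least-squares fit of S(b) = S_int exp(-b D) to
#' the b >= b_t portion of a decay curve: the first stage shared by all
#' segmented IVIM methods.
#'
#' @slot Dtilde fitted decay constant, mm^2/s (may exceed the true D when the
#'   tail is contaminated by residual pseudo-diffusion signal).
#' @slot Sint fitted y-intercept, intensity units.
#' @slot bt threshold used, s/mm^2.
#' @slot nPoints number of points entering the fit.
#' @seealso [fitMonoexp()]
#' @export
setClass("MonoExpFit",
  representation(Dtilde = "numeric", Sint = "numeric", bt = "numeric",
                 nPoints = "integer"))

setValidity("MonoExpFit", function(object) {
  if (!is.finite(object@Dtilde)) return("'Dtilde' must be finite")
  if (!is.finite(object@Sint) || object@Sint <= 0)
    return("'Sint' must be positive")
  TRUE
})

#' Pseudo-diffusion residual curve f~(b)
#'
#' The transformed curve f~(b) = 1 - (S(b)/S(0)) exp(b D) used by the
#' analytical segmented methods. With an exact D and no noise it equals
#' f (1 - exp(-b D*)); by construction f~(0) = 0 exactly. Values may be
#' negative under noise and are deliberately not clipped.
#'
#' @slot bvalues b-values, s/mm^2.
#' @slot ftilde f~(b), dimensionless.
#' @seealso [computeFTilde()]
#' @export
setClass("PseudoDiffusionCurve",
  representation(bvalues = "numeric", ftilde = "numeric"))

setValidity("PseudoDiffusionCurve", function(object) {
  if (length(object@bvalues) != length(object@ftilde))
    return("'bvalues' and 'ftilde' must have equal length")
  if (length(object@bvalues) && object@bvalues[1] == 0 &&
      object@ftilde[1] != 0)
    return("'ftilde' must be exactly 0 at b = 0")
  TRUE
})

#' Result of one IVIM curve fit
#'
#' @slot method one of `"S"`, `"OS"`, `"AS"`, `"opAS"`.
#' @slot params fitted \linkS4class{IVIMParams}; for AS/opAS the `f` slot
#'   carries f0, the asymptotic pseudo-diffusion fraction.
#' @slot intermediates named list of stage outputs, as applicable: `monoexp`
#'   (\linkS4class{MonoExpFit}), `f0`, `epsilon`, `ADC`, `fDproduct`
#'   (the f0*D* product from the threshold-extrapolation stage), `DstarTmp`.
#' @slot converged logical; `FALSE` means fallback values were returned.
#' @slot message diagnostic text (clips applied, optimizer status).
#' @seealso [fitCurve()]
#' @export
setClass("FitResult",
  representation(method = "character", params = "IVIMParams",
                 intermediates = "list", converged = "logical",
                 message = "character"))

setValidity("FitResult", function(object) {
  if (!object@method %in% c("S", "OS", "AS", "opAS"))
    return("'method' must be one of S, OS, AS, opAS")
  TRUE
})

#' Simulation study specification
#'
#' Conditions for the Rician-noise benchmarking study: a fixed
#' molecular-diffusion coefficient, grids of pseudo-diffusion fraction f and
#' pseudo-diffusion coefficient D*, the b-value sampling scheme, SNR levels
#' (S(0) divided by the Gaussian channel noise SD), and the replication
#' count. Defaults are the benchmark conditions: D = 1.0e-3 mm^2/s, f from
#' 0.02 to 0.50 in steps of 0.02, D* from 2e-3 to 60e-3 in steps of 2e-3
#' mm^2/s, 18 b-values (0, 20, 30, ..., 100, 150, 200, ..., 500 s/mm^2),
#' SNR 10/20/40, and 1000 replicates per cell.
#'
#' @slot D fixed molecular-diffusion coefficient, mm^2/s.
#' @slot fGrid grid of pseudo-diffusion fractions.
#' @slot DstarGrid grid of pseudo-diffusion coefficients, mm^2/s.
#' @slot bvalues b-value scheme, s/mm^2.
#' @slot snrLevels SNR levels.
#' @slot nReps replicates per grid cell.
#' @slot seed base random seed.
#' @export
setClass("SimulationSpec",
  representation(D = "numeric", fGrid = "numeric", DstarGrid = "numeric",
                 bvalues = "numeric", snrLevels = "numeric",
                 nReps = "integer", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- NULL
  if (any(object@fGrid <= 0) || any(object@fGrid > 1))
    msg <- c(msg, "'fGrid' values must be in (0, 1]")
  if (any(object@DstarGrid <= 0))
    msg <- c(msg, "'DstarGrid' values must be positive")
  if (any(object@snrLevels <= 0))
    msg <- c(msg, "'snrLevels' must be positive")
  if (object@nReps < 1L)
    msg <- c(msg, "'nReps' must be >= 1")
  v <- validObject(new("SignalCurve", bvalues = object@bvalues,
                       signal = rep(1, length(object@bvalues))), test = TRUE)
  if (!isTRUE(v))
    msg <- c(msg, "'bvalues' must satisfy the SignalCurve b-value contract")
  if (is.null(msg)) TRUE else msg
})

#' @param D fixed molecular-diffusion coefficient, mm^2/s.
#' @param fGrid grid of pseudo-diffusion fractions.
#' @param DstarGrid grid of pseudo-diffusion coefficients, mm^2/s.
#' @param bvalues b-value scheme, s/mm^2.
#' @param snrLevels SNR levels.
#' @param nReps replicates per grid cell.
#' @param seed base random seed.
#' @return `SimulationSpec()` returns a \linkS4class{SimulationSpec}.
#' @examples
#' SimulationSpec(nReps = 10)
#' @rdname SimulationSpec-class
#' @export
SimulationSpec <- function(D = 1.0e-3,
                           fGrid = seq(0.02, 0.50, by = 0.02),
                           DstarGrid = seq(2.0e-3, 60e-3, by = 2.0e-3),
                           bvalues = defaultBValues(),
                           snrLevels = c(10, 20, 40),
                           nReps = 1000L,
                           seed = 20250101L) {
  new("SimulationSpec", D = as.numeric(D), fGrid = as.numeric(fGrid),
      DstarGrid = as.numeric(DstarGrid), bvalues = as.numeric(bvalues),
      snrLevels = as.numeric(snrLevels), nReps = as.integer(nReps),
      seed = as.integer(seed))
}

#' Synthetic two-region phantom specification
#'
#' Geometry and tissue parameters for a synthetic diffusion-weighted volume
#' holding two disjoint ellipsoidal regions in a signal-free background: a
#' perfused "control" region and a low-perfusion "ischemic" region, emulating
#' a paired femoral-head acquisition. The default b-value scheme is the full
#' 18-value simulation scheme: the threshold-extrapolation stage of opAS
#' needs several thresholds beyond 100 s/mm^2 to be well identified at low
#' D*, which sparser clinical schemes cannot provide.
#'
#' @slot shape 3D voxel dimensions.
#' @slot control \linkS4class{IVIMParams} of the perfused region.
#' @slot ischemic \linkS4class{IVIMParams} of the non-perfused region.
#' @slot snr SNR of the added Rician noise (`Inf` for noiseless).
#' @slot bvalues b-value scheme, s/mm^2.
#' @slot centers 2 x 3 matrix of ellipsoid centers (voxel coordinates).
#' @slot radii 2 x 3 matrix of ellipsoid semi-axes (voxels).
#' @slot seed random seed.
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", control = "IVIMParams",
                 ischemic = "IVIMParams", snr = "numeric",
                 bvalues = "numeric", centers = "matrix", radii = "matrix",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "'shape' must be three positive integers")
  if (length(object@snr) != 1L || object@snr <= 0)
    msg <- c(msg, "'snr' must be a single positive number (Inf allowed)")
  if (!all(dim(object@centers) == c(2L, 3L)) ||
      !all(dim(object@radii) == c(2L, 3L)))
    msg <- c(msg, "'centers' and 'radii' must be 2 x 3 matrices")
  if (is.null(msg)) TRUE else msg
})

#' @param shape 3D voxel dimensions.
#' @param control perfused-region \linkS4class{IVIMParams}.
#' @param ischemic non-perfused-region \linkS4class{IVIMParams}.
#' @param snr SNR of the Rician noise; `Inf` for noiseless.
#' @param bvalues b-value scheme, s/mm^2.
#' @param centers optional 2 x 3 matrix of ellipsoid centers; default places
#'   the two regions side by side.
#' @param radii optional 2 x 3 matrix of semi-axes.
#' @param seed random seed.
#' @return `PhantomSpec()` returns a \linkS4class{PhantomSpec}.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(shape = c(20L, 20L, 3L),
                        control = IVIMParams(1.0e-3, 30e-3, 0.12),
                        ischemic = IVIMParams(1.6e-3, 5e-3, 0.03),
                        snr = 40,
                        bvalues = defaultBValues(),
                        centers = NULL,
                        radii = NULL,
                        seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(centers))
    centers <- rbind(c(0.30 * shape[1], 0.5 * shape[2], (shape[3] + 1) / 2),
                     c(0.70 * shape[1], 0.5 * shape[2], (shape[3] + 1) / 2))
  if (is.null(radii)) {
    r <- c(0.16 * shape[1], 0.20 * shape[2], max(1, 0.45 * shape[3]))
    radii <- rbind(r, r)
  }
  new("PhantomSpec", shape = shape, control = control, ischemic = ischemic,
      snr = as.numeric(snr), bvalues = as.numeric(bvalues),
      centers = unname(as.matrix(centers)), radii = unname(as.matrix(radii)),
      seed = as.integer(seed))
}

#' 4D diffusion-weighted volume
#'
#' A stack of 3D image volumes, one per b-value, with the b-values matched to
#' the 4th array axis. On construction the volumes are re-ordered so that
#' b-values are ascending; b = 0 must be present.
#'
#' @slot data 4D numeric array (x, y, z, b-index).
#' @slot bvalues b-values, s/mm^2, matched to the 4th axis.
#' @slot affine 4 x 4 spatial transform of the image grid.
#' @seealso [readDiffusionVolume()], [fitImage()]
#' @export
setClass("DiffusionVolume",
  representation(data = "array", bvalues = "numeric", affine = "matrix"))

setValidity("DiffusionVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4D array")
  else if (dim(object@data)[4] != length(object@bvalues))
    msg <- c(msg, "4th axis length must equal length(bvalues)")
  if (!any(object@bvalues == 0))
    msg <- c(msg, "'bvalues' must include 0")
  if (is.unsorted(object@bvalues, strictly = TRUE))
    msg <- c(msg, "'bvalues' must be strictly increasing after construction")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4 x 4 matrix")
  if (is.null(msg)) TRUE else msg
})

#' @param data 4D numeric array (x, y, z, b-index).
#' @param bvalues b-values matched to the 4th axis (any order; the volume is
#'   re-indexed to ascending b).
#' @param affine optional 4 x 4 spatial transform; identity by default.
#' @return `DiffusionVolume()` returns a \linkS4class{DiffusionVolume}.
#' @rdname DiffusionVolume-class
#' @export
DiffusionVolume <- function(data, bvalues, affine = diag(4)) {
  bvalues <- as.numeric(bvalues)
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, b-index)")
  if (dim(data)[4] != length(bvalues))
    stop("length(bvalues) must match the 4th array dimension")
  o <- order(bvalues)
  new("DiffusionVolume", data = data[, , , o, drop = FALSE],
      bvalues = bvalues[o], affine = as.matrix(affine))
}

#' Voxelwise IVIM parameter maps
#'
#' Output of [fitImage()]: one 3D map per IVIM parameter, with `NA` as the
#' sentinel for voxels outside the fitting mask or rejected as degenerate,
#' plus a logical convergence mask.
#'
#' @slot D,Dstar,f,flux 3D parameter maps (mm^2/s for D, D*, flux).
#' @slot converged logical 3D array; `FALSE` where the fit fell back or the
#'   voxel was not fitted.
#' @slot method fitting method used.
#' @slot options list of fitting options (b-threshold, mask rule).
#' @export
setClass("ParameterMaps",
  representation(D = "array", Dstar = "array", f = "array", flux = "array",
                 converged = "array", method = "character",
                 options = "list"))

setValidity("ParameterMaps", function(object) {
  d <- dim(object@D)
  for (nm in c("Dstar", "f", "flux", "converged"))
    if (!identical(dim(slot(object, nm)), d))
      return("all maps must share the same 3D shape")
  TRUE
})
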