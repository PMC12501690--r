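#' Read a 4D diffusion-weighted NIfTI volume
#'
#' Loads a 4D NIfTI file together with its FSL-style `.bval` sidecar (one
#' whitespace-separated row of b-values matched to the 4th axis). The
#' b-value order is taken from the sidecar, not assumed sorted; the volume
#' is re-indexed internally to ascending b.
#'
#' @param niftiPath path to the `.nii` / `.nii.gz` file.
#' @param bvalPath path to the `.bval` sidecar; defaults to `niftiPath`
#'   with the image extension replaced by `.bval`.
#' @return a \linkS4class{DiffusionVolume}.
#' @export
readDiffusionVolume <- function(niftiPath, bvalPath = NULL) {
  if (is.null(bvalPath))
    bvalPath <- paste0(sub("\\.nii(\\.gz)?$", "", niftiPath), ".bval")
  img <- RNifti::readNifti(niftiPath)
  bvals <- scan(bvalPath, quiet = TRUE)
  DiffusionVolume(as.array(img), bvals, affine = RNifti::xform(img))
}

#' Voxelwise IVIM map fitting
#'
#' Fits every in-mask voxel's decay curve with one method and assembles 3D
#' parameter maps. `NA` is the sentinel for voxels outside the mask or
#' rejected as degenerate (non-positive or non-finite S(0)); per-voxel fit
#' failures are recorded in the convergence mask and never abort the run.
#' Voxels are mutually independent and the fits are deterministic, so the
#' output does not depend on iteration order.
#'
#' @param volume a \linkS4class{DiffusionVolume}.
#' @param method one of `"S"`, `"OS"`, `"AS"`, `"opAS"`.
#' @param bt b-value threshold for the threshold-based methods, s/mm^2.
#' @param mask optional logical 3D array selecting voxels to fit. By
#'   default, voxels whose b = 0 intensity exceeds `maskFraction` of the
#'   in-volume 99th-percentile b = 0 intensity are fitted.
#' @param maskFraction fraction for the default mask rule.
#' @param verbose print a progress line every few thousand voxels.
#' @return a \linkS4class{ParameterMaps}.
#' @export
fitImage <- function(volume, method, bt = 100, mask = NULL,
                     maskFraction = 0.05, verbose = FALSE) {
  stopifnot(is(volume, "DiffusionVolume"))
  validObject(volume)
  shape <- dim(volume@data)[1:3]
  b0 <- volume@data[, , , which(volume@bvalues == 0)[1]]
  if (is.null(mask)) {
    ref <- stats::quantile(b0, 0.99, names = FALSE)
    mask <- b0 > maskFraction * ref
  }
  if (!identical(as.integer(dim(mask)), as.integer(shape)))
    stop("'mask' must match the spatial shape of the volume")
  empty <- array(NA_real_, dim = shape)
  maps <- list(D = empty, Dstar = empty, f = empty, flux = empty)
  conv <- array(FALSE, dim = shape)
  idx <- which(mask)
  nvox <- prod(shape)
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    ai <- arrayInd(i, shape)
    sig <- volume@data[ai[1], ai[2], ai[3], ]
    if (!all(is.finite(sig)) || sig[1] <= 0) next
    fr <- tryCatch({
      fitCurve(SignalCurve(volume@bvalues, sig), method, bt = bt)
    }, error = function(e) NULL)
    if (is.null(fr)) next
    maps$D[i] <- dCoef(fr); maps$Dstar[i] <- dStar(fr)
    maps$f[i] <- perfFraction(fr); maps$flux[i] <- perfFlux(fr)
    conv[i] <- fr@converged
    if (verbose && ii %% 2000 == 0)
      message(sprintf("fitImage[%s]: %d / %d voxels", method, ii,
                      length(idx)))
  }
  new("ParameterMaps", D = maps$D, Dstar = maps$Dstar, f = maps$f,
      flux = maps$flux, converged = conv, method = method,
      options = list(bt = if (method == "opAS") NA_real_ else bt,
                     maskFraction = maskFraction, nMask = length(idx),
                     nVoxels = nvox))
}

#' ROI medians of IVIM parameter maps
#'
#' Median of each parameter over the in-ROI voxels that were fitted and
#' converged; sentinel (`NA`) voxels are excluded first. Means over the same
#' voxels are attached as the `"means"` attribute for diagnostics.
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param roiMask logical 3D array.
#' @return named numeric vector with elements `D`, `Dstar`, `f`, `flux`.
#' @export
roiMedian <- function(maps, roiMask) {
  stopifnot(is(maps, "ParameterMaps"))
  use <- roiMask & maps@converged & !is.na(maps@D)
  if (!sum(use))
    stop("ROI contains no fitted, converged voxels")
  med <- c(D = stats::median(maps@D[use]),
           Dstar = stats::median(maps@Dstar[use]),
           f = stats::median(maps@f[use]),
           flux = stats::median(maps@flux[use]))
  attr(med, "means") <- c(D = mean(maps@D[use]),
                          Dstar = mean(maps@Dstar[use]),
                          f = mean(maps@f[use]),
                          flux = mean(maps@flux[use]))
  attr(med, "nVoxels") <- sum(use)
  med
}

#' Paired two-region comparison
#'
#' Two-sided paired t-test on per-subject differences `a - b` (e.g. ischemic
#' minus control ROI medians), using the sample (N-1) standard deviation of
#' the differences. With zero variance of the differences, the statistic is
#' 0 and p = 1 when the mean difference is 0 (with a note), and p = 0
#' otherwise.
#'
#' @param a,b equal-length numeric vectors of per-subject values (length
#'   >= 2).
#' @return list with `meanDiff`, `sdDiff`, `t`, `p`, `n`, `message`.
#' @examples
#' pairedCompare(c(2, 3, 4), c(1, 1, 1))
#' @export
pairedCompare <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired observations")
  d <- a - b
  n <- length(d)
  m <- mean(d); sdd <- stats::sd(d)
  if (sdd == 0) {
    if (m == 0)
      return(list(meanDiff = 0, sdDiff = 0, t = 0, p = 1, n = n,
                  message = "zero variance and zero mean difference"))
    return(list(meanDiff = m, sdDiff = 0, t = sign(m) * Inf, p = 0, n = n,
                message = "zero variance of differences"))
  }
  t <- m / (sdd / sqrt(n))
  list(meanDiff = m, sdDiff = sdd, t = t,
       p = 2 * stats::pt(-abs(t), df = n - 1), n = n, message = "")
}

#' Write parameter maps and a fitting report
#'
#' One NIfTI per parameter map plus the convergence mask, and a JSON report
#' of the method, options, voxel counts and convergence rate.
#'
#' @param maps a \linkS4class{ParameterMaps}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
writeParameterMaps <- function(maps, dir, prefix = "ivim") {
  stopifnot(is(maps, "ParameterMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("D", "Dstar", "f", "flux")) {
    p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", prefix, maps@method, nm))
    RNifti::writeNifti(RNifti::asNifti(slot(maps, nm)), p)
    paths[nm] <- p
  }
  p <- file.path(dir, sprintf("%s_%s_converged.nii.gz", prefix, maps@method))
  RNifti::writeNifti(RNifti::asNifti(maps@converged + 0), p)
  paths["converged"] <- p
  nFitted <- sum(!is.na(maps@D))
  report <- list(method = maps@method, options = maps@options,
                 nFitted = nFitted,
                 convergenceRate = if (nFitted)
                   sum(maps@converged) / nFitted else 0)
  rp <- file.path(dir, sprintf("%s_%s_report.json", prefix, maps@method))
  jsonlite::write_json(report, rp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["report"] <- rp
  invisible(paths)
}
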