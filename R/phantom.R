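#' Generate a synthetic two-region diffusion phantom
#'
#' Builds a 4D diffusion-weighted volume (one 3D volume per b-value) holding
#' two disjoint ellipsoidal regions in a signal-free background: a perfused
#' "control" region and a low-perfusion "ischemic" region, emulating a
#' paired femoral-head acquisition. Every in-region voxel follows its
#' region's IVIM decay with S(0) = 1; Rician noise at the requested SNR is
#' added everywhere (background voxels then sit at the Rayleigh noise
#' floor). The phantom is synthetic test data, not derived from any
#' acquisition.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements `volume` (a \linkS4class{DiffusionVolume}),
#'   `controlMask` and `ischemicMask` (logical 3D arrays), and `spec`.
#' @examples
#' ph <- generatePhantom(PhantomSpec(snr = Inf))
#' sum(ph$controlMask); sum(ph$ischemicMask)
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  shape <- spec@shape
  masks <- lapply(1:2, function(r)
    ellipsoidMask(shape, spec@centers[r, ], spec@radii[r, ]))
  if (any(masks[[1]] & masks[[2]]))
    stop("phantom region masks overlap; adjust centers/radii")
  if (!sum(masks[[1]]) || !sum(masks[[2]]))
    stop("phantom region masks must be non-empty")
  b <- spec@bvalues
  nb <- length(b)
  vol <- array(0, dim = c(shape, nb))
  sigControl <- ivimSignal(spec@control, b)
  sigIschemic <- ivimSignal(spec@ischemic, b)
  for (k in seq_len(nb)) {
    sl <- array(0, dim = shape)
    sl[masks[[1]]] <- sigControl[k]
    sl[masks[[2]]] <- sigIschemic[k]
    vol[, , , k] <- sl
  }
  withSeed(spec@seed, {
    if (is.finite(spec@snr)) {
      sigma <- 1 / spec@snr
      vol <- sqrt((vol + stats::rnorm(length(vol), 0, sigma))^2 +
                    stats::rnorm(length(vol), 0, sigma)^2)
    }
  })
  list(volume = DiffusionVolume(vol, b),
       controlMask = masks[[1]], ischemicMask = masks[[2]], spec = spec)
}

ellipsoidMask <- function(shape, center, radii) {
  x <- (seq_len(shape[1]) - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - center[2]) / radii[2]
  z <- (seq_len(shape[3]) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = shape)
}

#' Write a phantom to NIfTI files
#'
#' Writes the 4D volume (4th dimension = b-value index), the two region
#' masks, and an FSL-style `.bval` sidecar (one whitespace-separated row).
#'
#' @param phantom output of [generatePhantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
writePhantomNIfTI <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  RNifti::writeNifti(RNifti::asNifti(phantom$volume@data), p(".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$controlMask + 0), p("_control.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$ischemicMask + 0), p("_ischemic.nii.gz"))
  writeLines(paste(phantom$volume@bvalues, collapse = " "), p(".bval"))
  invisible(c(volume = p(".nii.gz"), control = p("_control.nii.gz"),
              ischemic = p("_ischemic.nii.gz"), bval = p(".bval")))
}
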