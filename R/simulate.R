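#' Add Rician noise to a magnitude MRI signal
#'
#' Implements the standard magnitude-MRI noise construction: each signal
#' value S is replaced by sqrt((S + n1)^2 + n2^2), where n1 and n2 are
#' independent zero-mean Gaussians with standard deviation
#' sigma = S0 / snr (SNR is defined as S(0) over the channel noise SD).
#' At low signal this distribution is Rayleigh-like and biases magnitudes
#' upward (the "Rician floor"); at high SNR it approaches a Gaussian of the
#' same sigma.
#'
#' @param signal non-negative signal intensities.
#' @param S0 reference intensity defining the noise scale (usually the
#'   noiseless S(0)).
#' @param snr signal-to-noise ratio; `Inf` returns the signal unchanged.
#' @param seed optional seed for a self-contained, reproducible draw; when
#'   `NULL` the current RNG stream is used.
#' @return noisy signal vector, strictly positive (almost surely).
#' @examples
#' s <- ivimSignal(IVIMParams(1e-3, 20e-3, 0.1), defaultBValues())
#' addRicianNoise(s, S0 = 1, snr = 20, seed = 1)
#' @export
addRicianNoise <- function(signal, S0 = 1, snr, seed = NULL) {
  signal <- as.numeric(signal)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("'signal' must be finite and non-negative")
  if (length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("'snr' must be a single positive number")
  if (length(S0) != 1L || !is.finite(S0) || S0 <= 0)
    stop("'S0' must be a single positive number")
  if (is.infinite(snr)) return(signal)
  sigma <- S0 / snr
  withSeed(seed, {
    n <- length(signal)
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  })
}

#' Simulate replicate noisy decay curves
#'
#' Generates `nReps` independent Rician-noise realizations of the noiseless
#' IVIM decay for one parameter combination, with S(0) normalized to 1
#' (all model parameters are scale-free, so this loses no generality).
#' Noise is drawn freshly for every replicate and every b-value.
#'
#' @param params true \linkS4class{IVIMParams}.
#' @param bvalues b-value scheme, s/mm^2.
#' @param snr signal-to-noise ratio; `Inf` gives noiseless curves.
#' @param nReps number of replicates.
#' @param seed optional seed; given the same seed the output is
#'   bit-reproducible.
#' @return list of `nReps` \linkS4class{SignalCurve} objects.
#' @examples
#' reps <- generateReplicates(IVIMParams(1e-3, 20e-3, 0.1),
#'                            snr = 20, nReps = 3, seed = 7)
#' @export
generateReplicates <- function(params, bvalues = defaultBValues(), snr,
                               nReps, seed = NULL) {
  stopifnot(is(params, "IVIMParams"))
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("'nReps' must be >= 1")
  clean <- ivimSignal(params, bvalues, S0 = 1)
  withSeed(seed, {
    lapply(seq_len(nReps), function(i) {
      SignalCurve(bvalues, addRicianNoise(clean, S0 = 1, snr = snr))
    })
  })
}

#' Write replicate curves to CSV
#'
#' Long format with columns `rep`, `b`, `signal`.
#'
#' @param curves list of \linkS4class{SignalCurve} objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeReplicatesCSV <- function(curves, path) {
  dt <- data.table::rbindlist(lapply(seq_along(curves), function(i) {
    data.table::data.table(rep = i, b = bValues(curves[[i]]),
                           signal = signalIntensities(curves[[i]]))
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a simulation specification from a JSON or YAML config file
#'
#' Recognized keys (all optional, with benchmark defaults): `D`, `f_grid`,
#' `Dstar_grid`, `bvalues`, `snr_levels`, `n_reps`, `seed`. Grids may be
#' given either as explicit vectors or as `{from, to, by}` maps.
#'
#' @param path config file; `.json`, `.yaml` or `.yml`.
#' @return a \linkS4class{SimulationSpec}.
#' @export
readSimulationConfig <- function(path) {
  cfg <- readConfigFile(path)
  grid <- function(x, default) {
    if (is.null(x)) return(default)
    if (is.list(x) && !is.null(x$from)) return(seq(x$from, x$to, by = x$by))
    as.numeric(unlist(x))
  }
  SimulationSpec(
    D = if (is.null(cfg[["D"]])) 1.0e-3 else cfg[["D"]],
    fGrid = grid(cfg[["f_grid"]], seq(0.02, 0.50, by = 0.02)),
    DstarGrid = grid(cfg[["Dstar_grid"]], seq(2.0e-3, 60e-3, by = 2.0e-3)),
    bvalues = grid(cfg[["bvalues"]], defaultBValues()),
    snrLevels = grid(cfg[["snr_levels"]], c(10, 20, 40)),
    nReps = if (is.null(cfg[["n_reps"]])) 1000L else
      as.integer(cfg[["n_reps"]]),
    seed = if (is.null(cfg[["seed"]])) 20250101L else
      as.integer(cfg[["seed"]]))
}

readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format: .", ext, " (use JSON or YAML)")
}
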