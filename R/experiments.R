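#' Run the Rician-noise simulation benchmark
#'
#' For every (f, D*, SNR) cell of the specification: generate `nReps`
#' replicate noisy curves, fit each with every requested method/threshold
#' combination, and tabulate NME / CoV / NRMSE per parameter. Each cell's
#' noise stream is seeded deterministically from the base seed and the cell's
#' parameter values (not its grid position), so thinning the grid changes
#' only sampling density, never the computation of a surviving cell, and a
#' rerun with the same seed is byte-identical.
#'
#' @param spec a \linkS4class{SimulationSpec}; thin the grids or lower
#'   `nReps` for reduced-scale runs.
#' @param methods data.frame with columns `method`, `bt` (see
#'   [defaultMethodGrid()]).
#' @param outDir optional output directory; when given, writes
#'   `estimates.csv`, `metrics.csv` and `provenance.json` (seed, spec hash,
#'   package version).
#' @param verbose print one line per grid cell.
#' @return list with `estimates` (one row per replicate x method),
#'   `metrics` (the [summarizeGrid()] table) and `provenance`.
#' @examples
#' spec <- SimulationSpec(fGrid = 0.1, DstarGrid = 30e-3, snrLevels = 40,
#'                        nReps = 5L, seed = 1L)
#' out <- runSimulationStudy(spec, methods = data.frame(method = "opAS",
#'                                                      bt = NA_real_))
#' @export
runSimulationStudy <- function(spec = SimulationSpec(),
                               methods = defaultMethodGrid(),
                               outDir = NULL, verbose = FALSE) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  .checkMethods(methods)
  cells <- expand.grid(f = spec@fGrid, Dstar = spec@DstarGrid,
                       snr = spec@snrLevels)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    fT <- cells$f[ci]; DsT <- cells$Dstar[ci]; snr <- cells$snr[ci]
    truth <- IVIMParams(spec@D, DsT, fT)
    reps <- generateReplicates(truth, spec@bvalues, snr, spec@nReps,
                               seed = cellSeed(spec@seed, fT, DsT, snr))
    cellRows <- vector("list", nrow(methods))
    for (mi in seq_len(nrow(methods))) {
      m <- methods$method[mi]; bt <- methods$bt[mi]
      fits <- lapply(reps, function(cv) {
        tryCatch(fitCurve(cv, m, bt = if (is.na(bt)) 100 else bt),
                 error = function(e) NULL)
      })
      ok <- !vapply(fits, is.null, TRUE)
      cellRows[[mi]] <- data.table::data.table(
        fTrue = fT, DstarTrue = DsT, DTrue = spec@D, snr = snr,
        method = m, bt = bt, rep = seq_along(fits),
        D = vapply(fits, function(x) if (is.null(x)) NA_real_ else dCoef(x), 0),
        Dstar = vapply(fits, function(x) if (is.null(x)) NA_real_ else dStar(x), 0),
        f = vapply(fits, function(x) if (is.null(x)) NA_real_ else perfFraction(x), 0),
        flux = vapply(fits, function(x) if (is.null(x)) NA_real_ else perfFlux(x), 0),
        converged = vapply(fits, function(x) !is.null(x) && x@converged, TRUE))
      if (any(!ok))
        warning(sum(!ok), " replicate fits failed in cell (f=", fT,
                ", D*=", DsT, ", snr=", snr, ", ", m, ")")
    }
    res[[ci]] <- data.table::rbindlist(cellRows)
    if (verbose)
      message(sprintf("cell %d/%d: f=%.2f D*=%.3g snr=%g", ci,
                      nrow(cells), fT, DsT, snr))
  }
  estimates <- as.data.frame(data.table::rbindlist(res))
  metrics <- summarizeGrid(estimates, spec)
  provenance <- list(
    seed = spec@seed,
    specHash = contentHash(list(spec@D, spec@fGrid, spec@DstarGrid,
                                spec@bvalues, spec@snrLevels, spec@nReps,
                                spec@seed, methods)),
    package = as.character(utils::packageVersion("ivimfit")),
    nCells = nrow(cells), nReps = spec@nReps)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(estimates, file.path(outDir, "estimates.csv"))
    data.table::fwrite(metrics, file.path(outDir, "metrics.csv"))
    jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(estimates = estimates, metrics = metrics, provenance = provenance)
}

.checkMethods <- function(methods) {
  if (!is.data.frame(methods) ||
      !all(c("method", "bt") %in% names(methods)))
    stop("'methods' must be a data.frame with columns method, bt")
  bad <- setdiff(methods$method, c("S", "OS", "AS", "opAS"))
  if (length(bad))
    stop("unknown method(s) in config: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Run a paired two-region phantom cohort study
#'
#' Synthetic analogue of a paired in-vivo comparison: generates `nSubjects`
#' two-region phantoms, fits each with every requested method, extracts ROI
#' medians for both regions and runs a paired t-test (ischemic minus
#' control) per method and parameter. Subject-to-subject biological
#' variability is emulated by lognormal jitter (coefficient of variation
#' `betweenSubjectCV`) applied independently to each region's D, D* and f
#' around the specified arm values; set it to 0 for identical subjects.
#'
#' @param nSubjects number of paired phantoms.
#' @param control,ischemic arm-level \linkS4class{IVIMParams}.
#' @param snr phantom SNR.
#' @param methods character vector of methods to fit.
#' @param bt threshold for the threshold-based methods, s/mm^2.
#' @param shape phantom voxel dimensions.
#' @param bvalues phantom b-value scheme.
#' @param betweenSubjectCV lognormal coefficient of variation of the
#'   per-subject true parameters.
#' @param seed base seed; subject phantoms and jitter derive from it.
#' @param verbose print one line per subject.
#' @return list with `medians` (per subject x method x region),
#'   `comparison` (per method x parameter: mean and SD of paired
#'   differences, t, p) and `truth` (per-subject true parameters).
#' @export
runPhantomStudy <- function(nSubjects = 11,
                            control = IVIMParams(1.0e-3, 30e-3, 0.12),
                            ischemic = IVIMParams(1.6e-3, 5e-3, 0.03),
                            snr = 40,
                            methods = c("S", "OS", "AS", "opAS"),
                            bt = 100,
                            shape = c(20L, 20L, 3L),
                            bvalues = defaultBValues(),
                            betweenSubjectCV = 0.15,
                            seed = 1L, verbose = FALSE) {
  .checkMethods(data.frame(method = methods, bt = NA_real_))
  sdlog <- sqrt(log(1 + betweenSubjectCV^2))
  jitter1 <- function(params) {
    g <- exp(stats::rnorm(3, -sdlog^2 / 2, sdlog))
    IVIMParams(dCoef(params) * g[1], dStar(params) * g[2],
               min(perfFraction(params) * g[3], 1))
  }
  medRows <- list(); truthRows <- list()
  for (si in seq_len(nSubjects)) {
    sSeed <- cellSeed(seed, 0.5, 1e-3, snr, extra = si)
    subj <- withSeed(sSeed, list(control = jitter1(control),
                                 ischemic = jitter1(ischemic)))
    ph <- generatePhantom(PhantomSpec(shape = shape, control = subj$control,
                                      ischemic = subj$ischemic, snr = snr,
                                      bvalues = bvalues,
                                      seed = cellSeed(sSeed, 0.1, 2e-3, snr)))
    roiMask <- ph$controlMask | ph$ischemicMask
    for (m in methods) {
      maps <- fitImage(ph$volume, m, bt = bt, mask = roiMask)
      for (region in c("control", "ischemic")) {
        med <- roiMedian(maps, if (region == "control") ph$controlMask
                               else ph$ischemicMask)
        medRows[[length(medRows) + 1L]] <- data.frame(
          subject = si, method = m, region = region,
          D = med["D"], Dstar = med["Dstar"], f = med["f"],
          flux = med["flux"], row.names = NULL)
      }
    }
    for (region in c("control", "ischemic")) {
      p <- subj[[region]]
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        subject = si, region = region, D = dCoef(p), Dstar = dStar(p),
        f = perfFraction(p), flux = perfFlux(p))
    }
    if (verbose) message("phantom subject ", si, "/", nSubjects)
  }
  medians <- do.call(rbind, medRows)
  cmpRows <- list()
  for (m in methods) for (pn in c("D", "Dstar", "f", "flux")) {
    a <- medians[medians$method == m & medians$region == "ischemic", pn]
    b <- medians[medians$method == m & medians$region == "control", pn]
    pc <- pairedCompare(a, b)
    cmpRows[[length(cmpRows) + 1L]] <- data.frame(
      method = m, parameter = pn, meanDiff = pc$meanDiff,
      sdDiff = pc$sdDiff, t = pc$t, p = pc$p, n = pc$n)
  }
  list(medians = medians, comparison = do.call(rbind, cmpRows),
       truth = do.call(rbind, truthRows))
}

#' Read an experiment configuration file
#'
#' JSON or YAML with two top-level sections: `simulation` (see
#' [readSimulationConfig()] keys) and `methods`, a list of
#' `{method, bt}` entries (b_t omitted or null for opAS). Unknown method
#' names raise a config error before any computation.
#'
#' @param path config file path.
#' @return list with `spec` (\linkS4class{SimulationSpec}) and `methods`
#'   (data.frame).
#' @export
readExperimentConfig <- function(path) {
  cfg <- readConfigFile(path)
  spec <- if (is.null(cfg$simulation)) SimulationSpec() else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg$simulation, tmp, auto_unbox = TRUE, digits = NA)
    readSimulationConfig(tmp)
  }
  methods <- if (is.null(cfg$methods)) defaultMethodGrid() else {
    mm <- cfg$methods
    if (is.data.frame(mm)) {
      if (is.null(mm$bt)) mm$bt <- NA_real_
      data.frame(method = as.character(mm$method), bt = as.numeric(mm$bt))
    } else {
      do.call(rbind, lapply(mm, function(e) data.frame(
        method = as.character(e$method),
        bt = if (is.null(e$bt)) NA_real_ else as.numeric(e$bt))))
    }
  }
  .checkMethods(methods)
  list(spec = spec, methods = methods)
}
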