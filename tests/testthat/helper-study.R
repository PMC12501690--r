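# Shared, memoised study runs for the acceptance suite (testthat loads
# helpers once per run, so these compute once even when used by several
# test blocks).

.studyCache <- new.env(parent = emptyenv())

reducedStudySpec <- function() {
  SimulationSpec(fGrid = c(0.02, 0.10, 0.26, 0.50),
                 DstarGrid = c(2e-3, 10e-3, 30e-3, 60e-3),
                 snrLevels = c(10, 40), nReps = 200L, seed = 20250101L)
}

getReducedStudy <- function() {
  if (is.null(.studyCache$study))
    .studyCache$study <- runSimulationStudy(reducedStudySpec())
  .studyCache$study
}

getPhantomCohort <- function(seed) {
  key <- paste0("cohort", seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- runPhantomStudy(seed = seed,
                                          bvalues = invivoBValues())
  .studyCache[[key]]
}

# mean over grid cells of |per-cell NME|, with NA-safe bt matching
meanAbsNME <- function(metrics, param, method, bt = NA, snr = NULL,
                       maxDstar = Inf) {
  r <- metrics[metrics$parameter == param & metrics$method == method &
                 (if (is.na(bt)) is.na(metrics$bt)
                  else !is.na(metrics$bt) & metrics$bt == bt) &
                 metrics$DstarTrue <= maxDstar, ]
  if (!is.null(snr)) r <- r[r$snr == snr, ]
  mean(abs(r$nme))
}

meanCoV <- function(metrics, param, method, bt = NA, snr) {
  r <- metrics[metrics$parameter == param & metrics$method == method &
                 (if (is.na(bt)) is.na(metrics$bt)
                  else !is.na(metrics$bt) & metrics$bt == bt) &
                 metrics$snr == snr, ]
  mean(r$cov)
}

# paired bootstrap of the gap in mean-|NME| between two method/threshold
# pairs; replicates are resampled identically for both methods (they share
# the underlying noisy curves), per cell
bootNMEGap <- function(estimates, param, methodA, btA, methodB, btB,
                       maxDstar = 10e-3, B = 200L, seed = 7L) {
  pick <- function(m, bt) {
    r <- estimates[estimates$method == m &
                     (if (is.na(bt)) is.na(estimates$bt)
                      else !is.na(estimates$bt) & estimates$bt == bt) &
                     estimates$DstarTrue <= maxDstar, ]
    truth <- switch(param, Dstar = r$DstarTrue, f = r$fTrue, D = r$DTrue,
                    flux = r$fTrue * r$DstarTrue)
    r$err <- (r[[param]] - truth) / truth
    split(r[order(r$rep), "err"],
          paste(r$fTrue, r$DstarTrue, r$snr)[order(r$rep)])
  }
  ea <- pick(methodA, btA); eb <- pick(methodB, btB)
  stopifnot(identical(names(ea), names(eb)))
  stat <- function(lst, idx) mean(vapply(seq_along(lst), function(i)
    abs(mean(lst[[i]][idx[[i]]])), 0))
  nrep <- length(ea[[1]])
  full <- lapply(seq_along(ea), function(i) seq_len(nrep))
  obs <- stat(eb, full) - stat(ea, full)
  set.seed(seed)
  gaps <- vapply(seq_len(B), function(b) {
    idx <- lapply(seq_along(ea), function(i) sample.int(nrep, replace = TRUE))
    stat(eb, idx) - stat(ea, idx)
  }, 0)
  list(gap = obs, se = stats::sd(gaps))
}
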