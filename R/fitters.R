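# Shared fitting bounds. D* and ADC in mm^2/s; f, f0 and epsilon
# dimensionless; P is the f0*D* product of the threshold-extrapolation
# stage. Kept generous relative to tissue values so boundary hits flag
# degenerate fits rather than constrain plausible ones.
.bounds <- list(
  f     = c(0, 1),
  Dstar = c(1e-5, 0.5),
  eps   = c(-0.5, 0.5),
  ADC   = c(1e-6, 1e-1),
  P     = c(0, 1e-1))

#' Mono-exponential fit of the high-b tail
#'
#' First stage of every segmented IVIM method: ordinary least squares of
#' log S(b) against b over the points with b >= `bt`, giving the decay
#' constant D-tilde and intercept S_int of S(b) = S_int exp(-b D). The log
#' fit is closed-form and deterministic. Non-positive signal values cannot
#' enter the log and are excluded; at least 3 usable points are required.
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param bt b-value threshold, s/mm^2.
#' @return a \linkS4class{MonoExpFit}.
#' @examples
#' cv <- SignalCurve(defaultBValues(),
#'                   ivimSignal(IVIMParams(1e-3, 60e-3, 0.1), defaultBValues()))
#' fitMonoexp(cv, bt = 200)
#' @export
fitMonoexp <- function(curve, bt) {
  stopifnot(is(curve, "SignalCurve"))
  b <- curve@bvalues; s <- curve@signal
  use <- b >= bt & s > 0
  n <- sum(use)
  if (n < 3L)
    stop(sprintf(
      "insufficient data: %d usable points with b >= %g (need >= 3)", n, bt))
  x <- b[use]; y <- log(s[use])
  sx <- sum(x); sy <- sum(y)
  slope <- (sum(x * y) - sx * sy / n) / (sum(x * x) - sx * sx / n)
  intercept <- (sy - slope * sx) / n
  new("MonoExpFit", Dtilde = -slope, Sint = exp(intercept),
      bt = as.numeric(bt), nPoints = as.integer(n))
}

#' Pseudo-diffusion residual curve
#'
#' Computes f~(b) = 1 - (S(b)/S(0)) exp(b D) for every acquired b-value.
#' With the exact D and no noise this equals f (1 - exp(-b D*)) identically;
#' f~(0) = 0 by construction. Noisy values may be negative and are retained
#' unclipped — the epsilon offset of the analytical fit absorbs S(0) error,
#' and clipping would bias f0.
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param D molecular-diffusion coefficient to factor out, mm^2/s.
#' @return a \linkS4class{PseudoDiffusionCurve}.
#' @export
computeFTilde <- function(curve, D) {
  stopifnot(is(curve, "SignalCurve"))
  if (length(D) != 1L || !is.finite(D) || D < 0)
    stop("'D' must be a single finite non-negative number")
  b <- curve@bvalues
  ft <- 1 - (curve@signal / curve@signal[1]) * exp(b * D)
  ft[b == 0] <- 0  # exact, not merely to rounding
  new("PseudoDiffusionCurve", bvalues = b, ftilde = ft)
}

# assemble a FitResult, clipping invalid parameter values into the
# IVIMParams domain and recording the clips
.makeResult <- function(method, D, Dstar, f, intermediates, converged,
                        message = "") {
  notes <- character(0)
  if (nzchar(message)) notes <- message
  if (D < 0) { notes <- c(notes, "D clipped to 0"); D <- 0 }
  if (f < 0 || f > 1) {
    notes <- c(notes, sprintf("f = %.4g clipped to [0, 1]", f))
    f <- clamp(f, 0, 1)
  }
  if (Dstar < 0) { notes <- c(notes, "D* clipped to 0"); Dstar <- 0 }
  new("FitResult", method = method,
      params = IVIMParams(D = D, Dstar = Dstar, f = f),
      intermediates = intermediates, converged = converged,
      message = paste(notes, collapse = "; "))
}

#' Segmented (S) IVIM fit
#'
#' Two stages: (1) D from the mono-exponential tail fit above `bt`
#' ([fitMonoexp()]); (2) bounded nonlinear least squares of the full
#' bi-exponential model over all b-values with D fixed and S(0) fixed at
#' the measured b = 0 signal, free parameters (f, D*).
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param bt b-value threshold, s/mm^2.
#' @return a \linkS4class{FitResult} with `method = "S"`. On optimizer
#'   failure the starting values are returned with `converged = FALSE`;
#'   no exception propagates.
#' @examples
#' b <- defaultBValues()
#' cv <- SignalCurve(b, ivimSignal(IVIMParams(1e-3, 60e-3, 0.2), b))
#' fitS(cv, bt = 200)
#' @export
fitS <- function(curve, bt) {
  stopifnot(is(curve, "SignalCurve"))
  mono <- fitMonoexp(curve, bt)
  D <- max(mono@Dtilde, 0)
  b <- curve@bvalues; s <- curve@signal; S0 <- s[1]
  start <- c(f = clamp(max(1 - mono@Sint / S0, 0.01), 0, 1),
             Dstar = clamp(10 * D, .bounds$Dstar[1], .bounds$Dstar[2]))
  fit <- boundedLS(start, function(p) {
    S0 * (p[1] * exp(-b * (D + p[2])) + (1 - p[1]) * exp(-b * D)) - s
  }, lower = c(.bounds$f[1], .bounds$Dstar[1]),
     upper = c(.bounds$f[2], .bounds$Dstar[2]))
  .makeResult("S", D = mono@Dtilde, Dstar = fit$par[2], f = fit$par[1],
              intermediates = list(monoexp = mono),
              converged = fit$converged, message = fit$message)
}

#' Oversegmented (OS) IVIM fit
#'
#' Stages: (1) D and S_int from [fitMonoexp()]; (2) f = 1 - S_int/S(0),
#' clipped into \[0, 1\]; (3) bounded nonlinear least squares of the
#' bi-exponential model with D and f fixed, sole free parameter D*.
#'
#' @inheritParams fitS
#' @return a \linkS4class{FitResult} with `method = "OS"`.
#' @export
fitOS <- function(curve, bt) {
  stopifnot(is(curve, "SignalCurve"))
  mono <- fitMonoexp(curve, bt)
  D <- max(mono@Dtilde, 0)
  b <- curve@bvalues; s <- curve@signal; S0 <- s[1]
  fRaw <- 1 - mono@Sint / S0
  f <- clamp(fRaw, 0, 1)
  clipNote <- if (fRaw < 0 || fRaw > 1)
    sprintf("f = %.4g from 1 - S_int/S(0) clipped to [0, 1]", fRaw) else ""
  if (f == 0) {
    # no perfusion compartment left: D* is unidentifiable, park it at the
    # lower bound rather than pretend to optimize a flat objective
    fit <- list(par = .bounds$Dstar[1], converged = TRUE, message = "")
  } else {
    start <- c(Dstar = clamp(10 * D, .bounds$Dstar[1], .bounds$Dstar[2]))
    fit <- boundedLS(start, function(p) {
      S0 * (f * exp(-b * (D + p[1])) + (1 - f) * exp(-b * D)) - s
    }, lower = .bounds$Dstar[1], upper = .bounds$Dstar[2])
  }
  msg <- paste(Filter(nzchar, c(clipNote, fit$message)), collapse = "; ")
  .makeResult("OS", D = mono@Dtilde, Dstar = fit$par[1], f = f,
              intermediates = list(monoexp = mono),
              converged = fit$converged, message = msg)
}

# stage shared by AS and opAS: bounded LS of
# ftilde(b) = f0 (1 - exp(-b D*)) + eps over all acquired b-values
.fitFTildeStage <- function(pd, f0Start, DstarStart) {
  b <- pd@bvalues; ft <- pd@ftilde
  start <- c(f0 = clamp(f0Start, 0, 1),
             Dstar = clamp(DstarStart, .bounds$Dstar[1], .bounds$Dstar[2]),
             eps = 0)
  boundedLS(start, function(p) {
    p[1] * (1 - exp(-b * p[2])) + p[3] - ft
  }, lower = c(.bounds$f[1], .bounds$Dstar[1], .bounds$eps[1]),
     upper = c(.bounds$f[2], .bounds$Dstar[2], .bounds$eps[2]))
}

#' Analytical segmented (AS) IVIM fit
#'
#' Stages: (1) D from [fitMonoexp()]; (2) the residual curve f~(b) from
#' [computeFTilde()]; (3) bounded nonlinear least squares of
#' f~(b) = f0 (1 - exp(-b D*)) + epsilon over all acquired b-values, free
#' parameters (f0, D*, epsilon). f0, the asymptotic pseudo-diffusion
#' fraction, is reported as the method's f estimate; epsilon absorbs error
#' in the measured S(0).
#'
#' @inheritParams fitS
#' @return a \linkS4class{FitResult} with `method = "AS"`; `intermediates`
#'   carries `monoexp`, `f0` and `epsilon`.
#' @export
fitAS <- function(curve, bt) {
  stopifnot(is(curve, "SignalCurve"))
  mono <- fitMonoexp(curve, bt)
  D <- max(mono@Dtilde, 0)
  pd <- computeFTilde(curve, D)
  fit <- .fitFTildeStage(pd, f0Start = max(1 - mono@Sint / curve@signal[1], 0.01),
                         DstarStart = 10 * D)
  .makeResult("AS", D = mono@Dtilde, Dstar = fit$par[2], f = fit$par[1],
              intermediates = list(monoexp = mono, f0 = unname(fit$par[1]),
                                   epsilon = unname(fit$par[3])),
              converged = fit$converged, message = fit$message)
}

#' Threshold-extrapolated D estimate (opAS stage 1)
#'
#' Computes the mono-exponential decay constant D-tilde(b_t) for a series of
#' thresholds, then fits
#' \deqn{\tilde D(b_t) = ADC - P (1 - e^{-b_t D^*_{tmp}})}
#' with free parameters (ADC, P, D*_tmp), where P plays the role of the
#' product f0 D*. As b_t grows the perfusion contamination of the tail fit
#' dies away, so the limit D = ADC - P is the threshold-free
#' molecular-diffusion estimate. D*_tmp is an internal shape parameter of
#' this stage and is discarded by [fitOpAS()] (the reported D* comes from
#' the analytical stage).
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param btSeries thresholds to scan; default every acquired b-value that
#'   leaves at least 4 points in the tail fit (for the 18-value scheme:
#'   0, 20, ..., 350 s/mm^2). At least 4 distinct thresholds are required.
#' @return list with `D` (= ADC - P), `ADC`, `fDproduct` (P), `DstarTmp`,
#'   `Dtilde` (the scanned series), `btSeries`, `converged` and `message`.
#'   P is capped at twice the span of the scanned series (an extrapolation
#'   cannot claim more decay than the thresholds evidence); if the fit runs
#'   to that cap, extrapolates below zero, or the optimizer fails, the
#'   method degrades gracefully to D = D-tilde(max b_t), flagged via
#'   `converged = FALSE`.
#' @export
estimateDopAS <- function(curve, btSeries = NULL) {
  stopifnot(is(curve, "SignalCurve"))
  b <- curve@bvalues
  if (is.null(btSeries)) {
    n <- length(b)
    btSeries <- b[seq_len(n - 3L)]
  }
  btSeries <- sort(unique(as.numeric(btSeries)))
  if (length(btSeries) < 4L)
    stop("insufficient data: need >= 4 distinct b_t values")
  Dt <- vapply(btSeries, function(bt) fitMonoexp(curve, bt)@Dtilde, 0)
  nb <- length(Dt)
  # The extrapolated decay magnitude P cannot credibly exceed (a small
  # multiple of) the span the scanned series actually exhibits; without
  # this cap the noisy problem has a degenerate near-linear optimum
  # (D*_tmp at its floor, P large) whose extrapolated D is far below any
  # evidence. The D*_tmp floor of 1e-3 mm^2/s encodes the IVIM premise
  # that pseudo-diffusion is not slower than tissue diffusion.
  Pmax <- min(max(2 * (max(Dt) - min(Dt)), 1e-5), .bounds$P[2])
  dstLower <- 1e-3
  start <- c(ADC = clamp(Dt[1], .bounds$ADC[1], .bounds$ADC[2]),
             P = clamp(max(Dt[1] - Dt[nb], 1e-6), .bounds$P[1], 0.5 * Pmax),
             DstarTmp = clamp(10 * max(Dt[nb], 1e-5),
                              dstLower, .bounds$Dstar[2]))
  fit <- boundedLS(start, function(p) {
    p[1] - p[2] * (1 - exp(-btSeries * p[3])) - Dt
  }, lower = c(.bounds$ADC[1], .bounds$P[1], dstLower),
     upper = c(.bounds$ADC[2], Pmax, .bounds$Dstar[2]))
  optError <- !fit$converged &&
    fit$message == "optimizer error; initial values returned"
  # a solution pinned at the P cap (or extrapolating below zero) means the
  # data do not support the extrapolation; degrade gracefully to the
  # largest-threshold tail estimate, flagged, instead of reporting an
  # extrapolation the series cannot evidence
  unsupported <- fit$par[2] >= Pmax * (1 - 1e-6) ||
    fit$par[1] - fit$par[2] < 0
  if (optError || unsupported) {
    return(list(D = max(Dt[nb], 0), ADC = unname(fit$par[1]),
                fDproduct = unname(fit$par[2]),
                DstarTmp = unname(fit$par[3]),
                Dtilde = Dt, btSeries = btSeries, converged = FALSE,
                message = if (optError)
                  "extrapolation failed; D taken at max b_t"
                else
                  "extrapolation unsupported by the threshold series; D taken at max b_t"))
  }
  list(D = unname(fit$par[1] - fit$par[2]), ADC = unname(fit$par[1]),
       fDproduct = unname(fit$par[2]), DstarTmp = unname(fit$par[3]),
       Dtilde = Dt, btSeries = btSeries, converged = fit$converged,
       message = fit$message)
}

#' Optimized analytical segmented (opAS) IVIM fit
#'
#' The threshold-free method: (1) D from the threshold-extrapolation of
#' [estimateDopAS()] — no b-threshold choice enters; (2) the residual curve
#' f~(b) with that D; (3) the analytical stage of [fitAS()] (f0, D*,
#' epsilon). Takes no `bt` argument by construction.
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param btSeries optional threshold series forwarded to
#'   [estimateDopAS()]; the default scans every acquired b-value leaving at
#'   least 4 tail points.
#' @return a \linkS4class{FitResult} with `method = "opAS"`;
#'   `intermediates` carries `ADC`, `fDproduct`, `DstarTmp`, `f0`,
#'   `epsilon`.
#' @examples
#' b <- defaultBValues()
#' cv <- SignalCurve(b, ivimSignal(IVIMParams(1e-3, 60e-3, 0.2), b))
#' fitOpAS(cv)
#' @export
fitOpAS <- function(curve, btSeries = NULL) {
  stopifnot(is(curve, "SignalCurve"))
  st1 <- estimateDopAS(curve, btSeries)
  pd <- computeFTilde(curve, st1$D)
  SintRef <- fitMonoexp(curve, max(st1$btSeries))@Sint
  fit <- .fitFTildeStage(pd, f0Start = max(1 - SintRef / curve@signal[1], 0.01),
                         DstarStart = 10 * st1$D)
  msg <- paste(Filter(nzchar, c(st1$message, fit$message)), collapse = "; ")
  .makeResult("opAS", D = st1$D, Dstar = fit$par[2], f = fit$par[1],
              intermediates = list(ADC = st1$ADC, fDproduct = st1$fDproduct,
                                   DstarTmp = st1$DstarTmp,
                                   f0 = unname(fit$par[1]),
                                   epsilon = unname(fit$par[3])),
              converged = st1$converged && fit$converged, message = msg)
}

#' Fit one curve with a named method
#'
#' Uniform dispatch over the four fitting approaches. `bt` applies to the
#' threshold-based methods (S, OS, AS) and is ignored by opAS, which is
#' threshold-free by construction.
#'
#' @param curve a \linkS4class{SignalCurve}.
#' @param method one of `"S"`, `"OS"`, `"AS"`, `"opAS"`.
#' @param bt b-value threshold for S/OS/AS, s/mm^2 (default 100).
#' @return a \linkS4class{FitResult}.
#' @examples
#' b <- defaultBValues()
#' cv <- SignalCurve(b, ivimSignal(IVIMParams(1e-3, 30e-3, 0.1), b))
#' fitCurve(cv, "opAS")
#' @export
fitCurve <- function(curve, method, bt = 100) {
  if (length(method) != 1L || !method %in% c("S", "OS", "AS", "opAS"))
    stop("unknown method '", paste(method, collapse = ","),
         "'; must be one of S, OS, AS, opAS")
  switch(method,
         S = fitS(curve, bt),
         OS = fitOS(curve, bt),
         AS = fitAS(curve, bt),
         opAS = fitOpAS(curve))
}

#' Default method/threshold combinations
#'
#' The benchmark set: S, OS and AS each at b_t = 100 and 200 s/mm^2, plus
#' the threshold-free opAS.
#'
#' @return data.frame with columns `method` and `bt` (`NA` for opAS).
#' @export
defaultMethodGrid <- function() {
  data.frame(method = c(rep(c("S", "OS", "AS"), each = 2), "opAS"),
             bt = c(rep(c(100, 200), 3), NA_real_),
             stringsAsFactors = FALSE)
}

#' Batch-fit a table of decay curves
#'
#' Fits every curve of a long-format table with one or more methods.
#' Per-curve failures are captured, not propagated: the affected row is
#' flagged `converged = FALSE` with the error in `message`.
#'
#' @param data data.frame with columns `id`, `b`, `signal` (one curve per
#'   id), or a path to such a CSV file.
#' @param methods data.frame with columns `method` and `bt` as from
#'   [defaultMethodGrid()], or a character vector of method names (then
#'   `bt` supplies the threshold).
#' @param bt threshold used when `methods` is a character vector.
#' @return data.frame with columns `id`, `method`, `bt`, `D`, `Dstar`, `f`,
#'   `flux`, `f0`, `epsilon`, `ADC`, `converged`, `message`.
#' @export
fitCurveTable <- function(data, methods = defaultMethodGrid(), bt = 100) {
  if (is.character(data) && length(data) == 1L)
    data <- data.table::fread(data)
  data <- as.data.frame(data)
  if (!all(c("id", "b", "signal") %in% names(data)))
    stop("'data' must have columns id, b, signal")
  if (is.character(methods))
    methods <- data.frame(method = methods,
                          bt = ifelse(methods == "opAS", NA_real_, bt))
  out <- vector("list", 0L)
  for (id in unique(data$id)) {
    sub <- data[data$id == id, ]
    curve <- tryCatch(SignalCurve(sub$b, sub$signal), error = identity)
    for (j in seq_len(nrow(methods))) {
      m <- methods$method[j]; btj <- methods$bt[j]
      row <- if (inherits(curve, "error"))
        .fitRow(id, m, btj, NULL, curve$message)
      else {
        fr <- tryCatch(fitCurve(curve, m, bt = if (is.na(btj)) 100 else btj),
                       error = identity)
        if (inherits(fr, "error")) .fitRow(id, m, btj, NULL, fr$message)
        else .fitRow(id, m, btj, fr)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

.fitRow <- function(id, method, bt, fr, errmsg = "") {
  if (is.null(fr)) {
    return(data.frame(id = id, method = method, bt = bt, D = NA_real_,
                      Dstar = NA_real_, f = NA_real_, flux = NA_real_,
                      f0 = NA_real_, epsilon = NA_real_, ADC = NA_real_,
                      converged = FALSE, message = errmsg,
                      stringsAsFactors = FALSE))
  }
  im <- fr@intermediates
  data.frame(id = id, method = method, bt = bt,
             D = dCoef(fr), Dstar = dStar(fr), f = perfFraction(fr),
             flux = perfFlux(fr),
             f0 = if (is.null(im$f0)) NA_real_ else im$f0,
             epsilon = if (is.null(im$epsilon)) NA_real_ else im$epsilon,
             ADC = if (is.null(im$ADC)) NA_real_ else im$ADC,
             converged = fr@converged, message = fr@message,
             stringsAsFactors = FALSE)
}
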