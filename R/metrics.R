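#' Estimator accuracy and precision metrics
#'
#' Benchmarking metrics over replicate estimates of one parameter with a
#' known true value theta_T:
#' \describe{
#'   \item{`nme()`}{normalized mean error, mean((theta_i - theta_T)/theta_T);
#'     signed, negative meaning underestimation.}
#'   \item{`coefVar()`}{coefficient of variation: the population (1/N)
#'     standard deviation about the sample mean, divided by the sample mean.
#'     The 1/N normalization (not 1/(N-1)) is deliberate and part of the
#'     metric definition.}
#'   \item{`nrmse()`}{normalized root-mean-square error,
#'     sqrt(mean((theta_i - theta_T)^2))/theta_T.}
#' }
#' The metrics satisfy nrmse >= |nme| and the exact decomposition
#' nrmse^2 = nme^2 + (population variance)/theta_T^2.
#'
#' @param values vector of replicate estimates.
#' @param truth true parameter value; must be non-zero.
#' @return a single numeric value.
#' @examples
#' nme(c(1.2, 1.0, 1.1), 1)    # 0.1
#' coefVar(c(1, 3))            # 0.5
#' nrmse(c(1.2, 0.8), 1)       # 0.2
#' @name error-metrics
NULL

#' @rdname error-metrics
#' @export
nme <- function(values, truth) {
  .checkSample(values)
  if (length(truth) != 1L || !is.finite(truth) || truth == 0)
    stop("'truth' must be a single non-zero finite number")
  mean((values - truth) / truth)
}

#' @rdname error-metrics
#' @export
coefVar <- function(values) {
  .checkSample(values)
  m <- mean(values)
  if (m == 0) stop("sample mean is zero; CoV undefined")
  sqrt(mean((values - m)^2)) / m
}

#' @rdname error-metrics
#' @export
nrmse <- function(values, truth) {
  .checkSample(values)
  if (length(truth) != 1L || !is.finite(truth) || truth == 0)
    stop("'truth' must be a single non-zero finite number")
  sqrt(mean((values - truth)^2)) / abs(truth)
}

.checkSample <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    stop("'values' must be a non-empty vector of finite numbers")
}

#' Tabulate error metrics over a simulation grid
#'
#' Aggregates replicate fit results into one row of NME / CoV / NRMSE per
#' (parameter, f, D*, SNR, method, b_t) combination — the long format behind
#' the benchmark heatmaps (f increasing vertically, D* horizontally).
#'
#' @param estimates data.frame of replicate estimates as produced by
#'   [runSimulationStudy()], with columns `fTrue`, `DstarTrue`, `DTrue`,
#'   `snr`, `method`, `bt`, `rep`, `D`, `Dstar`, `f`, `flux`, `converged`.
#' @param spec optional \linkS4class{SimulationSpec}; when given, grid cells
#'   with no results are listed in the `missingCells` attribute of the
#'   result (a completeness report) rather than silently dropped.
#' @param excludeNonConverged if `TRUE`, replicates whose fit fell back are
#'   excluded before computing metrics (sensitivity analysis); the default
#'   includes them.
#' @return data.frame with columns `parameter` (`D`, `Dstar`, `f`, `flux`),
#'   `fTrue`, `DstarTrue`, `snr`, `method`, `bt`, `nme`, `cov`, `nrmse`,
#'   `n`. Truths are `DTrue`, `DstarTrue`, `fTrue` and their product for
#'   `flux`.
#' @export
summarizeGrid <- function(estimates, spec = NULL,
                          excludeNonConverged = FALSE) {
  dt <- data.table::as.data.table(estimates)
  need <- c("fTrue", "DstarTrue", "DTrue", "snr", "method", "bt", "D",
            "Dstar", "f", "flux", "converged")
  if (!all(need %in% names(dt)))
    stop("'estimates' lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  if (excludeNonConverged) dt <- dt[dt$converged == TRUE, ]
  long <- data.table::rbindlist(lapply(
    c("D", "Dstar", "f", "flux"), function(pn) {
      truth <- switch(pn, D = dt$DTrue, Dstar = dt$DstarTrue, f = dt$fTrue,
                      flux = dt$fTrue * dt$DstarTrue)
      data.table::data.table(parameter = pn, fTrue = dt$fTrue,
                             DstarTrue = dt$DstarTrue, snr = dt$snr,
                             method = dt$method, bt = dt$bt,
                             value = dt[[pn]], truth = truth)
    }))
  out <- long[, {
    v <- value[is.finite(value)]
    if (length(v)) {
      m <- mean(v)
      list(nme = mean((v - truth[1]) / truth[1]),
           cov = if (m == 0) NA_real_ else sqrt(mean((v - m)^2)) / m,
           nrmse = sqrt(mean((v - truth[1])^2)) / abs(truth[1]),
           n = length(v))
    } else list(nme = NA_real_, cov = NA_real_, nrmse = NA_real_, n = 0L)
  }, by = c("parameter", "fTrue", "DstarTrue", "snr", "method", "bt")]
  out <- as.data.frame(out)
  if (!is.null(spec)) {
    expected <- expand.grid(fTrue = spec@fGrid, DstarTrue = spec@DstarGrid,
                            snr = spec@snrLevels)
    have <- unique(out[c("fTrue", "DstarTrue", "snr")])
    key <- function(d) paste(d$fTrue, d$DstarTrue, d$snr)
    missing <- expected[!key(expected) %in% key(have), , drop = FALSE]
    attr(out, "missingCells") <- missing
    if (nrow(missing))
      warning(nrow(missing), " expected grid cells have no results; ",
              "see attr(, 'missingCells')")
  }
  out
}

#' Render a metric table as a parameter-grid heatmap
#'
#' Convenience plot of one metric for one parameter in the benchmark
#' orientation: f increasing vertically, D* horizontally, one facet per
#' (method, SNR). Requires ggplot2.
#'
#' @param metrics output of [summarizeGrid()].
#' @param parameter one of `"D"`, `"Dstar"`, `"f"`, `"flux"`.
#' @param metric one of `"nme"`, `"cov"`, `"nrmse"`.
#' @return a ggplot object.
#' @export
plotMetricGrid <- function(metrics, parameter = "Dstar", metric = "nme") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotMetricGrid requires the ggplot2 package")
  d <- metrics[metrics$parameter == parameter, ]
  d$label <- ifelse(is.na(d$bt), d$method, paste0(d$method, " bt=", d$bt))
  d$metricValue <- d[[metric]]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(DstarTrue * 1e3),
                                  y = factor(fTrue),
                                  fill = metricValue)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(snr ~ label) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "D* (1e-3 mm^2/s)", y = "f",
                  fill = paste0(metric, "(", parameter, ")"))
}
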