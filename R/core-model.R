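#' Standard b-value schemes
#'
#' `defaultBValues()` returns the 18-value simulation scheme
#' (0, 20, 30, ..., 100, 150, 200, ..., 500 s/mm^2); `invivoBValues()` the
#' 13-value subset used for in-vivo style acquisitions
#' (0, 20, 30, ..., 100, 200, 300, 500 s/mm^2).
#'
#' @return numeric vector of b-values, s/mm^2.
#' @export
defaultBValues <- function() {
  c(seq(0, 100, by = 10)[-2], seq(150, 500, by = 50))
}

#' @rdname defaultBValues
#' @export
invivoBValues <- function() {
  c(seq(0, 100, by = 10)[-2], 200, 300, 500)
}

#' Bi-exponential IVIM forward signal model
#'
#' Evaluates the two-compartment (tissue + vascular) IVIM decay
#' \deqn{S(b) = S(0) [ f e^{-b(D + D^*)} + (1 - f) e^{-bD} ]}
#' at the given b-values. Note the perfusion compartment decays with
#' D + D*, so the apparent diffusion coefficient of the curve at b = 0 is
#' exactly D + f D* (see [adcAtOrigin()]).
#'
#' @param params an \linkS4class{IVIMParams}.
#' @param bvalues non-negative b-values, s/mm^2.
#' @param S0 signal at b = 0; must be positive.
#' @return vector of signal intensities, one per b-value; values lie in
#'   (0, S0] and decrease monotonically in b.
#' @examples
#' ivimSignal(IVIMParams(1e-3, 10e-3, 0.1), c(0, 100, 500))
#' @export
ivimSignal <- function(params, bvalues, S0 = 1) {
  stopifnot(is(params, "IVIMParams"))
  validObject(params)
  bvalues <- as.numeric(bvalues)
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("'bvalues' must be finite and non-negative")
  if (length(S0) != 1L || !is.finite(S0) || S0 <= 0)
    stop("'S0' must be a single positive number")
  f <- params@f
  S0 * (f * exp(-bvalues * (params@D + params@Dstar)) +
        (1 - f) * exp(-bvalues * params@D))
}

#' Apparent diffusion coefficient at b = 0
#'
#' The negative initial slope of the normalized IVIM decay,
#' -d(S(b)/S(0))/db at b = 0, which for the bi-exponential model equals
#' D + f D*. This is the ADC to which a mono-exponential fit tends as the
#' fitted b-range shrinks to the origin, and the quantity the opAS method
#' extrapolates from its threshold series.
#'
#' @param params an \linkS4class{IVIMParams}.
#' @return ADC in mm^2/s.
#' @examples
#' adcAtOrigin(IVIMParams(1e-3, 10e-3, 0.1))  # 2e-3
#' @export
adcAtOrigin <- function(params) {
  stopifnot(is(params, "IVIMParams"))
  validObject(params)
  params@D + params@f * params@Dstar
}
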