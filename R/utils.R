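# internal helpers

.datatable.aware <- TRUE

# evaluate expr under a temporary RNG state; restores the caller's state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-cell seed derived from parameter values, not grid
# indices, so thinning a grid never changes a surviving cell's stream
cellSeed <- function(seed, f, Dstar, snr, extra = 0L) {
  k <- (as.numeric(seed) %% 65011) * 33029 +
    round(f * 1e4) * 7919 + round(Dstar * 1e7) * 104729 +
    round(min(snr, 1e6)) * 1299709 + as.numeric(extra) * 15485863
  as.integer(k %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# bounded Levenberg-Marquardt least squares; never throws.
# residFn(par) returns the residual vector. On optimizer error the start
# values are returned with converged = FALSE.
boundedLS <- function(par, residFn, lower, upper, maxiter = 100L) {
  par <- clamp(par, lower, upper)
  # nls.lm warns when it stops at maxiter; that state is read from
  # fit$info and reported through the converged flag instead
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par, fn = residFn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = par, converged = FALSE,
                message = "optimizer error; initial values returned"))
  ok <- fit$info %in% 1:3
  list(par = clamp(coef(fit), lower, upper), converged = ok,
       message = if (ok) "" else
         sprintf("optimizer stopped without convergence (info = %d)",
                 fit$info))
}

# order-insensitive content hash (djb2 over the serialized text) used for
# provenance records; not cryptographic
contentHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
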