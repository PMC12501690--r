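test_that("mono-exponential tail fit is exact on mono-exponential data", {
  b <- defaultBValues()
  cv <- SignalCurve(b, exp(-b * 1e-3))
  for (bt in c(0, 100, 200)) {
    m <- fitMonoexp(cv, bt)
    expect_equal(m@Dtilde, 1e-3, tolerance = 1e-12)
    expect_equal(m@Sint, 1, tolerance = 1e-12)
  }
})

test_that("tail fit contamination behaves as the segmentation assumes", {
  # fast pseudo-diffusion (D* = 60e-3), bt = 200: residual perfusion term
  # is ~5e-6 of the signal, so D-tilde lands within 0.5% of D
  cv <- makeCurve(1e-3, 60e-3, 0.1)
  expect_equal(fitMonoexp(cv, 200)@Dtilde, 1e-3, tolerance = 5e-3)

  # slow pseudo-diffusion (D* = 4e-3), bt = 100: perfusion still decays in
  # the tail, inflating the fitted decay constant
  cv <- makeCurve(1e-3, 4e-3, 0.3)
  expect_gt(fitMonoexp(cv, 100)@Dtilde, 1e-3)
})

test_that("tail fit enforces data requirements", {
  b <- defaultBValues()
  cv <- SignalCurve(b, exp(-b * 1e-3))
  expect_error(fitMonoexp(cv, 450), "insufficient")
  # non-positive signals are excluded from the log fit
  s <- exp(-b * 1e-3); s[16:18] <- -0.01
  cv2 <- SignalCurve(b, s)
  m <- fitMonoexp(cv2, 200)
  expect_identical(m@nPoints, 4L)   # 200, 250, 300, 350 remain
  expect_error(fitMonoexp(cv2, 300), "insufficient")
})

test_that("f-tilde transform satisfies its algebraic identity", {
  b <- defaultBValues()
  # worked value: f (1 - e^(-b D*)) at f=0.1, D*=10e-3, b=100
  cv <- makeCurve(1e-3, 10e-3, 0.1)
  pd <- computeFTilde(cv, 1e-3)
  expect_equal(ftilde(pd)[bValues(pd) == 100], 0.063212,
               tolerance = 1e-5)
  expect_identical(ftilde(pd)[1], 0)

  set.seed(17)
  for (i in 1:25) {
    D <- runif(1, 2e-4, 3e-3); Ds <- runif(1, 1e-3, 0.1)
    f <- runif(1, 0.01, 0.99)
    pd <- computeFTilde(makeCurve(D, Ds, f), D)
    expect_equal(ftilde(pd), f * (1 - exp(-b * Ds)), tolerance = 1e-10)
  }

  # f = 0 with the exact D gives the all-zero curve
  pd0 <- computeFTilde(makeCurve(1e-3, 30e-3, 0), 1e-3)
  expect_equal(ftilde(pd0), rep(0, length(b)), tolerance = 1e-14)
})

test_that("S method recovers noiseless parameters and matches the oracle", {
  cv <- makeCurve(1e-3, 60e-3, 0.2)
  fit <- fitS(cv, bt = 200)
  expect_true(isConverged(fit))
  expect_equal(perfFraction(fit), 0.2, tolerance = 0.01)
  expect_equal(dStar(fit), 60e-3, tolerance = 0.02)

  # independent dense grid-search oracle for the stage-2 objective
  D <- max(intermediates(fit)$monoexp@Dtilde, 0)
  or <- oracleS2(cv, D)
  expect_equal(perfFraction(fit), or$f, tolerance = 0.01)
  expect_equal(dStar(fit), or$Dstar, tolerance = 0.02)

  # pure mono-exponential data: nothing for the perfusion term to explain
  cv0 <- makeCurve(1e-3, 30e-3, 0)
  expect_lte(perfFraction(fitS(cv0, 100)), 1e-3)

  # low-D* contamination pushes f down (the classic failure mode)
  cvLow <- makeCurve(1e-3, 4e-3, 0.1)
  expect_lt(perfFraction(fitS(cvLow, 100)), 0.1)
})

test_that("OS method computes f from the intercept and fits only D*", {
  cv <- makeCurve(1e-3, 60e-3, 0.2)
  fit <- fitOS(cv, bt = 200)
  mono <- intermediates(fit)$monoexp
  expect_equal(perfFraction(fit), 1 - mono@Sint / s0(cv), tolerance = 1e-12)
  expect_equal(perfFraction(fit), 0.2, tolerance = 0.01)
  expect_equal(dStar(fit), 60e-3, tolerance = 0.02)
  or <- oracleOS2(cv, max(mono@Dtilde, 0), perfFraction(fit))
  expect_equal(dStar(fit), or, tolerance = 0.02)

  # S_int above S(0): f clips to 0, flagged but still converged
  b <- defaultBValues()
  s <- 0.95 * exp(-b * 1e-3); s[1] <- 0.90
  clipFit <- fitOS(SignalCurve(b, s), bt = 100)
  expect_identical(perfFraction(clipFit), 0)
  expect_match(clipFit@message, "clip")
  expect_lte(dStar(clipFit), 1e-4)
})

test_that("AS method fits the f-tilde curve with an epsilon offset", {
  cv <- makeCurve(1e-3, 60e-3, 0.2)
  fit <- fitAS(cv, bt = 200)
  expect_equal(perfFraction(fit), 0.2, tolerance = 0.01)
  expect_equal(dStar(fit), 60e-3, tolerance = 0.02)
  expect_lte(abs(intermediates(fit)$epsilon), 1e-4)
  expect_identical(perfFraction(fit), intermediates(fit)$f0)

  # oracle cross-check of the analytical stage
  D <- max(intermediates(fit)$monoexp@Dtilde, 0)
  or <- oracleFTilde(computeFTilde(cv, D))
  expect_equal(perfFraction(fit), or$f0, tolerance = 0.02)
  expect_equal(dStar(fit), or$Dstar, tolerance = 0.05)

  # all-zero f-tilde: everything collapses to zero
  fit0 <- fitAS(makeCurve(1e-3, 30e-3, 0), bt = 100)
  expect_lte(perfFraction(fit0), 1e-6)
  expect_lte(abs(intermediates(fit0)$epsilon), 1e-6)

  # constant f-tilde for b > 0 is only reachable as D* -> infinity
  b <- defaultBValues()
  s <- 0.9 * exp(-b * 1e-3); s[1] <- 1
  fitC <- fitAS(SignalCurve(b, s), bt = 100)
  expect_true(dStar(fitC) >= 0.4 || !isConverged(fitC))
})

test_that("threshold extrapolation recovers D and the origin ADC", {
  # f = 0: the D-tilde series is flat and D = ADC = true D
  cv0 <- makeCurve(1e-3, 30e-3, 0)
  st <- estimateDopAS(cv0)
  expect_equal(st$D, 1e-3, tolerance = 1e-6)
  expect_equal(st$ADC, 1e-3, tolerance = 1e-4)
  expect_lte(st$fDproduct, 1e-7)
  expect_equal(st$Dtilde, rep(1e-3, length(st$btSeries)), tolerance = 1e-10)

  # the fitted ADC approximates D + f D* (a b -> 0 tangent, not exact)
  st2 <- estimateDopAS(makeCurve(1e-3, 30e-3, 0.1))
  expect_equal(st2$ADC, 4.0e-3, tolerance = 0.10)

  # oracle cross-check of the extrapolation stage at a low-D* cell
  cv3 <- makeCurve(1e-3, 8e-3, 0.3)
  st3 <- estimateDopAS(cv3)
  or <- oracleDExtrap(st3$btSeries, st3$Dtilde)
  expect_equal(st3$D, or$D, tolerance = 0.02)

  expect_error(estimateDopAS(cv0, btSeries = c(0, 100, 200)),
               "insufficient")
})

test_that("opAS is threshold-free and accurate on noiseless curves", {
  cv <- makeCurve(1e-3, 60e-3, 0.2)
  fit <- fitOpAS(cv)
  expect_equal(dCoef(fit), 1e-3, tolerance = 0.02)
  expect_equal(dStar(fit), 60e-3, tolerance = 0.02)
  expect_equal(perfFraction(fit), 0.2, tolerance = 0.02)

  # f = 0: exact D, essentially no perfusion fraction
  fit0 <- fitOpAS(makeCurve(1e-3, 30e-3, 0))
  expect_equal(dCoef(fit0), 1e-3, tolerance = 1e-4)
  expect_lte(perfFraction(fit0), 1e-3)

  # the dispatcher's bt option must not touch opAS output
  r1 <- fitCurve(cv, "opAS", bt = 50)
  r2 <- fitCurve(cv, "opAS", bt = 300)
  expect_identical(fittedParams(r1), fittedParams(r2))
  expect_identical(fittedParams(r1), fittedParams(fitOpAS(cv)))
})

test_that("opAS beats the threshold methods where thresholds fail", {
  # slow pseudo-diffusion regime: at bt = 100 the tail fit is contaminated
  cv <- makeCurve(1e-3, 4e-3, 0.1)
  op <- fitOpAS(cv); s <- fitS(cv, 100); as_ <- fitAS(cv, 100)
  for (get in list(dStar, perfFraction)) {
    truth <- if (identical(get, dStar)) 4e-3 else 0.1
    expect_lt(abs(relErr(get(op), truth)), abs(relErr(get(s), truth)))
    expect_lt(abs(relErr(get(op), truth)), abs(relErr(get(as_), truth)))
  }
})

test_that("tail-fit error shrinks monotonically with bt at low D*", {
  for (Ds in c(2e-3, 4e-3, 6e-3)) for (f in c(0.1, 0.3)) {
    cv <- makeCurve(1e-3, Ds, f)
    bts <- defaultBValues()[1:15]
    err <- vapply(bts, function(bt) abs(fitMonoexp(cv, bt)@Dtilde - 1e-3), 0)
    expect_true(all(diff(err) <= 1e-12))
  }
})

test_that("method dispatch validates its arguments", {
  cv <- makeCurve(1e-3, 30e-3, 0.1)
  expect_error(fitCurve(cv, "bayes"), "unknown method")
  s1 <- fitCurve(cv, "S", bt = 100)
  s2 <- fitS(cv, 100)
  expect_identical(fittedParams(s1), fittedParams(s2))
  o1 <- fitCurve(cv, "OS", bt = 200)
  expect_identical(fittedParams(o1), fittedParams(fitOS(cv, 200)))
})

test_that("fitters survive noisy degenerate inputs without exceptions", {
  set.seed(3)
  b <- defaultBValues()
  for (i in 1:20) {
    # near-floor curves: tiny true signal, heavy Rician noise
    s <- addRicianNoise(ivimSignal(IVIMParams(2e-3, 2e-3, 0.02), b) * 0.05,
                        S0 = 0.05, snr = 5)
    cv <- SignalCurve(b, s)
    for (m in c("S", "OS", "AS", "opAS")) {
      fit <- fitCurve(cv, m, bt = 100)
      expect_s4_class(fit, "FitResult")
      expect_true(is.finite(dCoef(fit)) && is.finite(dStar(fit)) &&
                    is.finite(perfFraction(fit)))
      expect_true(perfFraction(fit) >= 0 && perfFraction(fit) <= 1)
    }
  }
})

test_that("batch fitting produces the tidy contract and captures failures", {
  b <- defaultBValues()
  good <- ivimSignal(IVIMParams(1e-3, 30e-3, 0.15), b)
  tab <- rbind(data.frame(id = "ok", b = b, signal = good),
               data.frame(id = "dead", b = b, signal = rep(0, length(b))))
  out <- fitCurveTable(tab, methods = data.frame(
    method = c("S", "opAS"), bt = c(100, NA)))
  expect_identical(nrow(out), 4L)
  expect_true(all(c("id", "method", "bt", "D", "Dstar", "f", "flux", "f0",
                    "epsilon", "ADC", "converged", "message") %in%
                    names(out)))
  okRows <- out[out$id == "ok", ]
  expect_true(all(okRows$converged))
  expect_equal(okRows$flux, okRows$f * okRows$Dstar, tolerance = 1e-12)
  deadRows <- out[out$id == "dead", ]
  expect_true(all(!deadRows$converged))
  expect_true(all(is.na(deadRows$D)))
})
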