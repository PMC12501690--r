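makeSingleVoxelVolume <- function(curve) {
  nb <- length(bValues(curve))
  DiffusionVolume(array(signalIntensities(curve), dim = c(1, 1, 1, nb)),
                  bValues(curve))
}

test_that("volume construction re-indexes to ascending b", {
  b <- invivoBValues()
  s <- ivimSignal(IVIMParams(1e-3, 20e-3, 0.1), b)
  shuffled <- c(5, 1, 3, 2, 4, 6:length(b))
  vol <- DiffusionVolume(array(rep(s[shuffled], each = 8),
                               dim = c(2, 2, 2, length(b))),
                         b[shuffled])
  expect_identical(vol@bvalues, b)
  expect_equal(vol@data[1, 1, 1, ], s)
  expect_error(DiffusionVolume(array(1, dim = c(2, 2, 2, 3)),
                               c(10, 20, 30)),
               "include 0")
})

test_that("single-voxel image fit equals the curve fit", {
  cv <- makeCurve(1e-3, 30e-3, 0.12, bvalues = invivoBValues(),
                  snr = 40, seed = 5)
  vol <- makeSingleVoxelVolume(cv)
  for (m in c("S", "opAS")) {
    maps <- fitImage(vol, m, bt = 100,
                     mask = array(TRUE, dim = c(1, 1, 1)))
    ref <- fitCurve(cv, m, bt = 100)
    expect_equal(maps@D[1, 1, 1], dCoef(ref))
    expect_equal(maps@Dstar[1, 1, 1], dStar(ref))
    expect_equal(maps@f[1, 1, 1], perfFraction(ref))
    expect_equal(maps@flux[1, 1, 1], perfFlux(ref))
  }
})

test_that("degenerate voxels get sentinels, never exceptions", {
  b <- invivoBValues()
  dat <- array(0, dim = c(2, 1, 1, length(b)))
  dat[1, 1, 1, ] <- ivimSignal(IVIMParams(1e-3, 20e-3, 0.1), b)
  # voxel 2 is all-zero
  vol <- DiffusionVolume(dat, b)
  maps <- fitImage(vol, "opAS", mask = array(TRUE, dim = c(2, 1, 1)))
  expect_true(is.na(maps@D[2, 1, 1]))
  expect_false(maps@converged[2, 1, 1])
  expect_true(is.finite(maps@D[1, 1, 1]))
  expect_true(maps@converged[1, 1, 1])
})

test_that("map fitting is independent of voxel order", {
  ph <- generatePhantom(PhantomSpec(shape = c(10L, 10L, 2L), snr = 20,
                                    seed = 9))
  vol <- ph$volume
  perm <- rev(seq_len(dim(vol@data)[1]))
  volPerm <- DiffusionVolume(vol@data[perm, , , , drop = FALSE],
                             vol@bvalues)
  m1 <- fitImage(vol, "AS", bt = 100)
  m2 <- fitImage(volPerm, "AS", bt = 100)
  expect_identical(m2@D[perm, , ], m1@D)
  expect_identical(m2@Dstar[perm, , ], m1@Dstar)
})

test_that("ROI medians exclude sentinels and use the median", {
  shape <- c(3L, 1L, 1L)
  mk <- function(v) array(v, dim = shape)
  maps <- new("ParameterMaps",
              D = mk(c(1e-3, 2e-3, 9e-3)), Dstar = mk(c(1, 2, 9) * 1e-2),
              f = mk(c(0.1, 0.2, 0.9)), flux = mk(c(1, 2, 9) * 1e-3),
              converged = mk(rep(TRUE, 3)), method = "opAS",
              options = list())
  roi <- mk(rep(TRUE, 3))
  expect_equal(roiMedian(maps, roi)[["D"]], 2e-3)

  # sentinel voxel is dropped before the median
  maps@D[3] <- NA_real_
  expect_equal(roiMedian(maps, roi)[["Dstar"]], 1.5e-2)

  # non-converged voxels are dropped too
  maps@converged[2] <- FALSE
  expect_equal(roiMedian(maps, roi)[["D"]], 1e-3)
  maps@converged[] <- FALSE
  expect_error(roiMedian(maps, roi), "no fitted")
})

test_that("paired comparison matches textbook arithmetic and t.test", {
  pc <- pairedCompare(c(2, 3, 4), c(1, 1, 1))
  expect_equal(pc$meanDiff, 2)
  expect_equal(pc$sdDiff, 1)
  expect_equal(pc$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)

  # zero-variance branch
  same <- pairedCompare(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_match(same$message, "zero variance")

  # oracle: stats::t.test on random paired data
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    ref <- t.test(a, b, paired = TRUE)
    pc <- pairedCompare(a, b)
    expect_equal(pc$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pc$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pairedCompare(1:3, 1:4), "equal length")
  expect_error(pairedCompare(1, 2), "at least 2")
})

test_that("noiseless phantom round-trips through the opAS pipeline", {
  ph <- generatePhantom(PhantomSpec(snr = Inf, seed = 1))
  maps <- fitImage(ph$volume, "opAS",
                   mask = ph$controlMask | ph$ischemicMask)
  ctrl <- roiMedian(maps, ph$controlMask)
  isch <- roiMedian(maps, ph$ischemicMask)
  truthC <- ph$spec@control; truthI <- ph$spec@ischemic
  expect_equal(ctrl[["D"]], dCoef(truthC), tolerance = 0.05)
  expect_equal(ctrl[["Dstar"]], dStar(truthC), tolerance = 0.05)
  expect_equal(ctrl[["f"]], perfFraction(truthC), tolerance = 0.05)
  # ischemic-vs-control ordering of all four parameters
  expect_gt(isch[["D"]], ctrl[["D"]])
  expect_lt(isch[["Dstar"]], ctrl[["Dstar"]])
  expect_lt(isch[["f"]], ctrl[["f"]])
  expect_lt(isch[["flux"]], ctrl[["flux"]])
})

test_that("parameter maps and report are written to disk", {
  dir <- withr::local_tempdir()
  ph <- generatePhantom(PhantomSpec(shape = c(8L, 8L, 2L), snr = 40,
                                    seed = 4))
  maps <- fitImage(ph$volume, "S", bt = 100, mask = ph$controlMask)
  paths <- writeParameterMaps(maps, dir)
  expect_true(all(file.exists(paths)))
  report <- jsonlite::read_json(paths[["report"]])
  expect_identical(report$method, "S")
  expect_true(report$nFitted > 0)
  back <- as.array(RNifti::readNifti(paths[["D"]]))
  expect_equal(sum(!is.na(back) & back != 0), sum(!is.na(maps@D)),
               tolerance = 0)
})
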