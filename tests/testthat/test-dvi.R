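# DVI core: reference selection, unwrapping, regression, conversion,
# full computation against phantom ground truth, profiles and noise floors.

test_that("reference pixel is the in-window amplitude maximum", {
  a <- rep(1, 100); a[52] <- 9
  expect_equal(selectReferencePixel(a, 50), 52L)
  b <- rep(1, 100); b[c(48, 53)] <- 7
  expect_equal(selectReferencePixel(b, 50), 48L)   # tie -> smaller row
  c0 <- rep(1, 100); c0[80] <- 50; c0[55] <- 5
  expect_equal(selectReferencePixel(c0, 50), 55L)  # out-of-window max ignored
  expect_error(selectReferencePixel(a[1:5], 200, 10), "window")
})

test_that("temporal unwrapping matches the brute-force 2pi-shift oracle", {
  s <- c(0, 2.5, -1.3)
  expect_equal(temporalUnwrap(s), bruteForceUnwrap(s))
  expect_equal(temporalUnwrap(s)[3], 2.5 + (-1.3 - 2.5) + 2 * pi)
  expect_equal(temporalUnwrap(rep(0.7, 6)), rep(0.7, 6))
  ramp <- seq(0, by = 0.4, length.out = 12)
  expect_equal(temporalUnwrap(dvioct:::wrapPhase(ramp)), ramp)
  set.seed(5)
  for (i in 1:25) {
    x <- cumsum(runif(8, -pi + 1e-6, pi - 1e-6))
    w <- dvioct:::wrapPhase(x)
    expect_equal(temporalUnwrap(w), x, tolerance = 1e-12)
    expect_equal(temporalUnwrap(w), bruteForceUnwrap(w), tolerance = 1e-12)
  }
})

test_that("phase rate equals the closed-form OLS slope", {
  expect_equal(phaseRate(c(0, 0.5, 1, 1.5), c(0, 0.5, 1, 1.5)), 1)
  tau <- c(0, 0.5, 1, 1.5, 2)
  line <- 2 + 0.8 * tau
  eps <- 0.3 * c(1, -1, 0, -1, 1)   # orthogonal to the centred design
  expect_equal(phaseRate(line + eps, tau), 0.8)
  set.seed(2)
  for (i in 1:20) {
    y <- rnorm(10); t <- sort(runif(10))
    expect_equal(phaseRate(y, t),
                 sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2),
                 tolerance = 1e-12)
  }
  expect_error(phaseRate(c(1, 2), c(3, 3)), "timestamps")
})

test_that("velocity conversion and Nyquist cap follow the phase relations", {
  expect_equal(velocityFromPhaseRate(0), 0)
  expect_equal(velocityFromPhaseRate(pi, 800, 1.37), 800 / (4 * 1.37))
  expect_equal(velocityFromPhaseRate(1, 800, 2.74),
               velocityFromPhaseRate(1, 800, 1.37) / 2)
  expect_equal(nyquistVelocity(800, n = 1.37, frameRate = 2),
               800 * 2 / (4 * 1.37))
  expect_equal(nyquistVelocity(800, n = 1, frameRate = 2), 400)
  expect_equal(nyquistVelocity(1300, n = 1.37, frameRate = 10),
               1300 * 10 / (4 * 1.37))
  expect_equal(nyquistVelocity(AcquisitionGeometry()),
               nyquistVelocity(800, n = 1.37, frameRate = 2))
})

test_that("a 2pi-larger per-frame phase step is indistinguishable (aliasing)", {
  tau <- (0:9) / 2
  step <- 1.1
  s1 <- dvioct:::wrapPhase(step * (0:9))
  s2 <- dvioct:::wrapPhase((step + 2 * pi) * (0:9))
  expect_equal(temporalUnwrap(s1), temporalUnwrap(s2), tolerance = 1e-12)
  expect_equal(phaseRate(temporalUnwrap(s1), tau),
               phaseRate(temporalUnwrap(s2), tau), tolerance = 1e-12)
})

test_that("noiseless phantoms are recovered exactly, for every field kind", {
  geom <- smallGeometry()
  kinds <- list(
    makeDeformationField("rigid", list(bulk_nm_s = 100)),
    makeDeformationField("uniform_strain", list(strain_rate = -2e-4)),
    makeDeformationField("exponential_front",
      list(v_boundary_nm_s = -200, decay_um = 80,
           z_boundary_um = 139 * 5.2 / 1.37)))
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 31)
  seg <- NULL
  for (f in kinds) {
    st <- renderFrameStack(sc, f, geom, seed = 32)
    if (is.null(seg)) seg <- segmentCornea(amplitudeImage(st),
                                           segmentationConfig())
    dvi <- computeDVI(st, seg)
    tru <- groundTruthVelocity(st, referenceRows(dvi))
    err <- abs(velocityImage(dvi) - tru)[validMask(dvi)]
    expect_lt(max(err, na.rm = TRUE), 1e-6)
    # the reference pixel itself reads zero before smoothing
    refV <- velocityImage(dvi)[cbind(referenceRows(dvi),
                                     seq_along(referenceRows(dvi)))]
    expect_lt(max(abs(refV), na.rm = TRUE), 1e-9)
  }
})

test_that("bulk motion is removed by reference subtraction", {
  geom <- smallGeometry()
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 33)
  f0 <- makeDeformationField("uniform_strain", list(strain_rate = -1e-4))
  f1 <- makeDeformationField("uniform_strain",
                             list(strain_rate = -1e-4, bulk_nm_s = 200))
  s0 <- renderFrameStack(sc, f0, geom, seed = 34)
  s1 <- renderFrameStack(sc, f1, geom, seed = 34)
  seg <- segmentCornea(amplitudeImage(s0), segmentationConfig())
  d0 <- computeDVI(s0, seg); d1 <- computeDVI(s1, seg)
  expect_lt(max(abs(velocityImage(d0) - velocityImage(d1)), na.rm = TRUE),
            1e-6)
})

test_that("uniform strain appears as a linear axial profile of slope s", {
  geom <- smallGeometry()
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 35)
  f <- makeDeformationField("uniform_strain", list(strain_rate = -2e-4))
  st <- renderFrameStack(sc, f, geom, seed = 36)
  seg <- segmentCornea(amplitudeImage(st), segmentationConfig())
  dvi <- computeDVI(st, seg)
  pr <- axialProfile(dvi, seg)
  # distance runs against depth, so the profile slope is -s
  sl <- stats::coef(stats::lm(pr@meanVelocity ~ pr@distanceUm))[2] * 1e-3
  expect_equal(unname(sl), 2e-4, tolerance = 0.01)
  expect_equal(length(pr@distanceUm),
               max(posteriorPath(seg) - anteriorPath(seg)) + 1L)
})

test_that("axial profile of a uniform image is constant", {
  geom <- smallGeometry()
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 37)
  st <- renderFrameStack(sc, makeDeformationField("rigid",
                         list(bulk_nm_s = 50)), geom, seed = 38)
  seg <- segmentCornea(amplitudeImage(st), segmentationConfig())
  dvi <- computeDVI(st, seg)
  pr <- axialProfile(dvi, seg)
  expect_lt(max(abs(pr@meanVelocity)), 1e-9)
})

test_that("boxcar smoothing lowers the per-pixel error under noise", {
  geom <- smallGeometry()
  sc <- makeCornealScene(layout = smallLayout(), snr = 20, seed = 39)
  f <- makeDeformationField("exponential_front",
        list(v_boundary_nm_s = -150, decay_um = 100,
             z_boundary_um = 139 * 5.2 / 1.37))
  st <- renderFrameStack(sc, f, geom, seed = 40)
  seg <- segmentCornea(amplitudeImage(st), segmentationConfig())
  dvi <- computeDVI(st, seg)
  tru <- groundTruthVelocity(st, referenceRows(dvi))
  sel <- validMask(dvi)
  rmse <- function(x) sqrt(mean((x - tru)[sel]^2, na.rm = TRUE))
  expect_lt(rmse(velocityImage(dvi, smoothed = TRUE)),
            rmse(velocityImage(dvi)))
})

test_that("noise floors vanish without noise and order under averaging", {
  geom <- smallGeometry()
  sc0 <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 41)
  st0 <- renderFrameStack(sc0, makeDeformationField("static"), geom,
                          seed = 42)
  seg0 <- segmentCornea(amplitudeImage(st0), segmentationConfig())
  d0 <- computeDVI(st0, seg0)
  expect_lt(noiseFloor(d0, "raw"), 1e-9)
  expect_lt(noiseFloor(d0, "smoothed"), 1e-9)
  expect_lt(noiseFloor(d0, "axial_averaged", interfaces = seg0), 1e-9)

  sc <- makeCornealScene(layout = smallLayout(), snr = 10, seed = 43)
  st <- renderFrameStack(sc, makeDeformationField("static"), geom, seed = 44)
  seg <- segmentCornea(amplitudeImage(st), segmentationConfig())
  d <- computeDVI(st, seg)
  fr <- noiseFloor(d, "raw")
  fs <- noiseFloor(d, "smoothed")
  fa <- noiseFloor(d, "axial_averaged", interfaces = seg)
  expect_gt(fr, fs); expect_gt(fs, fa)
  expect_error(noiseFloor(d, "raw", region = matrix(FALSE, 200, 60)),
               "too small")
})

test_that("measurement window and medium corrections do the bookkeeping", {
  expect_equal(measurementWindow(AcquisitionGeometry()), 5)
  expect_equal(opticalToGeometric(12), 12 / 1.37)
  expect_equal(round(opticalToGeometric(12)), 9)
  expect_equal(round(opticalToGeometric(5.2), 1), 3.8)
})
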