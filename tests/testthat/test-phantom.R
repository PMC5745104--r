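# Phantom simulator: scene construction, deformation fields, and the
# phase contract of the renderer.

test_that("flat layout places truth paths at the requested rows", {
  sc <- makeCornealScene(layout = smallLayout(anteriorRow = 100,
                                              thicknessPx = 200,
                                              nrow = 360L,
                                              wallRows = c(15, 340),
                                              curvaturePx = 0),
                         seed = 1)
  expect_true(all(sc@truth$anterior == 100))
  expect_true(all(sc@truth$posterior == 300))
})

test_that("identical seeds give bit-identical phantoms and stacks", {
  a <- makeCornealScene(layout = smallLayout(), snr = 10, seed = 42)
  b <- makeCornealScene(layout = smallLayout(), snr = 10, seed = 42)
  expect_identical(a@amplitude, b@amplitude)
  geom <- smallGeometry(nFrames = 4L)
  f <- makeDeformationField("uniform_strain", list(strain_rate = -1e-4))
  s1 <- renderFrameStack(a, f, geom, seed = 7)
  s2 <- renderFrameStack(b, f, geom, seed = 7)
  expect_identical(s1@frames, s2@frames)
})

test_that("overlapping or out-of-frame interfaces are rejected", {
  expect_error(makeCornealScene(layout = smallLayout(thicknessPx = -10)),
               "overlap|invalid")
  expect_error(makeCornealScene(layout = smallLayout(anteriorRow = 190)),
               "invalid layout")
  expect_error(makeCornealScene(snr = 0), "snr")
})

test_that("stromal contrast over the noise floor grows with SNR", {
  geom <- smallGeometry(nFrames = 2L)
  ratios <- vapply(c(0.01, 1, 100), function(snr) {
    sc <- makeCornealScene(layout = smallLayout(), snr = snr, seed = 3)
    st <- renderFrameStack(sc, makeDeformationField("static"), geom, seed = 4)
    amp <- amplitudeImage(st)
    stroma <- amp[90:120, ]                      # inside the cornea
    bg <- amp[160:180, ]                         # below posterior, above wall
    mean(stroma) / mean(bg)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("deformation field kinds evaluate per their definitions", {
  f <- makeDeformationField("uniform_strain",
                            list(strain_rate = -1e-4, z_ref_um = 0))
  expect_equal(f@velocityFun(500, 0, 0), -50)
  r <- makeDeformationField("rigid", list(bulk_nm_s = 100))
  expect_equal(r@velocityFun(c(0, 250, 800), 0, 0), c(0, 0, 0))
  expect_equal(r@bulkFun(10), 100)
  s <- makeDeformationField("static")
  expect_equal(s@bulkFun(3), 0)
  expect_error(makeDeformationField("spiral"), "unknown")
})

test_that("model_trajectory fields reproduce the model velocity profile", {
  p <- deswellParams(nElements = 20L)
  tr <- simulateDeswell(p, 1800, seq(0, 1800, length.out = 31))
  f <- makeDeformationField("model_trajectory",
                            list(trajectory = tr, z_anterior_um = 0))
  t0 <- 1200
  mp <- modelVelocityProfile(tr, t0)
  # field depth is measured from the anterior face; the profile from the
  # posterior face
  tt <- max(mp@distanceUm)
  got <- f@velocityFun(tt - mp@distanceUm, 0, t0)
  expect_equal(got, mp@meanVelocity, tolerance = 1e-6)
})

test_that("renderer phase steps follow 4 pi n v dt / lambda", {
  geom <- smallGeometry(nFrames = 5L)   # 800 nm, n 1.37, 2 Hz
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 5)
  f <- makeDeformationField("rigid", list(bulk_nm_s = 146))
  st <- renderFrameStack(sc, f, geom, seed = 6)
  ph <- Arg(st@frames[100, 30, ])
  steps <- diff(temporalUnwrap(ph))
  expect_equal(steps, rep(4 * pi * 1.37 * 146 * 0.5 / 800, 4),
               tolerance = 1e-9)
  expect_lt(abs(steps[1] - pi / 2), 0.01)
  # uniform motion: every in-cornea pixel of an A-scan shares the step
  ph2 <- Arg(st@frames[120, 30, ])
  expect_equal(diff(temporalUnwrap(ph2)), steps, tolerance = 1e-9)
})

test_that("static noiseless stacks repeat frame 1 exactly", {
  geom <- smallGeometry(nFrames = 3L)
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 8)
  st <- renderFrameStack(sc, makeDeformationField("static"), geom, seed = 9)
  expect_identical(st@frames[, , 1], st@frames[, , 2])
  expect_identical(st@frames[, , 1], st@frames[, , 3])
})

test_that("noiseless unwrapped phase equals the displacement contract", {
  geom <- smallGeometry(nFrames = 10L)
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 10)
  f <- makeDeformationField("exponential_front",
         list(v_boundary_nm_s = -150, decay_um = 80,
              z_boundary_um = 140 * 5.2 / 1.37))
  st <- renderFrameStack(sc, f, geom, seed = 11)
  pitch <- geom@axialPitchAir / geom@groupIndex
  for (px in list(c(60, 10), c(100, 40), c(135, 55))) {
    z <- (px[1] - 1) * pitch
    v <- f@velocityFun(z, 0, 0)
    ph <- temporalUnwrap(Arg(st@frames[px[1], px[2], ]))
    expected <- 4 * pi * 1.37 / 800 * v * st@timestamps
    expect_equal(ph - ph[1], expected - expected[1], tolerance = 1e-9)
  }
})

test_that("displacement exceeding the axial range is rejected", {
  geom <- smallGeometry(nFrames = 3L)
  sc <- makeCornealScene(layout = smallLayout(), snr = Inf, seed = 12)
  f <- makeDeformationField("rigid", list(bulk_nm_s = 5e9))
  expect_error(renderFrameStack(sc, f, geom, seed = 1), "axial range")
})
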