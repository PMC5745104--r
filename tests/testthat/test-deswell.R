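# Osmotic de-swelling model: pressure law, Euler stepping (R reference vs
# compiled integrator), conservation, equilibria and velocity profiles.

test_that("swelling pressure is a positive, strictly decreasing power law", {
  expect_error(swellingPressure(-1), "hydration")
  H <- seq(0.5, 12, by = 0.25)
  Pi <- swellingPressure(H)
  expect_true(all(Pi > 0))
  expect_true(all(diff(Pi) < 0))
  # gamma = 1: doubling hydration halves the pressure
  expect_equal(swellingPressure(4, C = 1e6, gamma = 1),
               swellingPressure(2, C = 1e6, gamma = 1) / 2)
  # documented reference constant is accepted as-is
  p <- deswellParams(C = 2.41e6)
  expect_equal(p@C, 2.41e6)
  expect_equal(p@piExt, 2.41e6 / 2.44^2)
})

test_that("closed uniform systems are stationary", {
  st <- new("ModelState", hydration = rep(5, 10), time = 0)
  pClosed <- deswellParams(Lendo = 0, H0 = 5, Heq = 2.44, nElements = 10L)
  out <- stepDeswell(st, pClosed, 10)
  expect_equal(out@hydration, st@hydration)
  # at the equilibrium hydration the boundary flux also vanishes
  pEq <- deswellParams(H0 = 2.44, Heq = 2.44, nElements = 10L)
  stEq <- new("ModelState", hydration = rep(2.44, 10), time = 0)
  expect_equal(stepDeswell(stEq, pEq, 5)@hydration, stEq@hydration)
  trEq <- simulateDeswell(pEq, 600)
  expect_equal(max(abs(trEq@hydration - 2.44)), 0)
})

test_that("one explicit step drains only the posterior element", {
  p <- deswellParams(nElements = 8L)
  st <- new("ModelState", hydration = rep(p@H0, 8), time = 0)
  dt <- 0.004
  out <- stepDeswell(st, p, dt)
  delta <- p@dryThickness / 8
  expectedLoss <- dt * p@Lendo * (p@piExt - swellingPressure(p@H0)) / delta
  expect_equal(out@hydration[8], p@H0 - expectedLoss, tolerance = 1e-12)
  expect_equal(out@hydration[1:7], rep(p@H0, 7))
  expect_equal(out@time, dt)
})

test_that("the compiled integrator reproduces the R reference stepper", {
  p <- deswellParams(nElements = 12L)
  dt <- 0.005; n <- 200
  H <- rep(p@H0, 12)
  st <- new("ModelState", hydration = H, time = 0)
  for (i in seq_len(n)) st <- stepDeswell(st, p, dt)
  tr <- simulateDeswell(p, n * dt, sampleTimes = c(0, n * dt), dt = dt)
  expect_equal(st@hydration, as.vector(tr@hydration[, 2]), tolerance = 1e-12)
})

test_that("negative hydration from an oversized step is caught", {
  p <- deswellParams(Lendo = 1e-6, nElements = 4L)
  st <- new("ModelState", hydration = rep(p@H0, 4), time = 0)
  expect_error(stepDeswell(st, p, 1e4), "negative hydration")
})

test_that("water is conserved and the scheme converges", {
  p <- deswellParams()
  tr <- simulateDeswell(p, 3600)
  delta <- p@dryThickness / p@nElements
  W <- delta * colSums(tr@hydration)
  removed <- W[1] - W[length(W)]
  consErr <- max(abs((W[1] - W) - colSums(tr@outflux)))
  expect_lt(consErr / removed, 1e-3)       # global bookkeeping
  expect_lt(consErr / removed, 1e-10)      # in practice machine precision
  # thickness falls strictly while the bath stays hypertonic
  expect_true(all(diff(tr@thickness) < 0))
  # dt halving and N doubling barely move the endpoint
  tr2 <- simulateDeswell(p, 3600, dt = stabilityDt(p) / 2)
  expect_lt(abs(tr2@thickness[41] - tr@thickness[41]) / tr@thickness[41],
            1e-3)
  trN <- simulateDeswell(deswellParams(nElements = 100L), 3600)
  expect_lt(abs(trN@thickness[41] - tr@thickness[41]) / tr@thickness[41],
            5e-3)
})

test_that("velocity profiles are anchored at the anterior reference", {
  p <- deswellParams()
  tr <- simulateDeswell(p, 3600, seq(0, 3600, length.out = 41))
  early <- modelVelocityProfile(tr, 400)
  late <- modelVelocityProfile(tr, 3000)
  # zero at the anterior face (largest distance from the endothelium)
  expect_equal(early@meanVelocity[length(early@meanVelocity)], 0)
  # the fastest motion sits at the posterior face early in de-swelling
  expect_equal(which.max(abs(early@meanVelocity)), 1L)
  expect_true(all(early@meanVelocity <= 0))
  expect_gt(max(abs(early@meanVelocity)), max(abs(late@meanVelocity)))
  expect_error(modelVelocityProfile(tr, 1e6), "outside")
})

test_that("a leaky endothelium equilibrates its element on internal timescales", {
  pFast <- deswellParams(Lendo = 179e-9)   # 1000x reference conductivity
  tr <- simulateDeswell(pFast, 120, seq(0, 120, length.out = 5))
  HN <- tr@hydration[pFast@nElements, 5]
  H1 <- tr@hydration[1, 5]
  expect_lt(abs(HN - pFast@Heq), 0.4)      # boundary element near the bath
  expect_gt(H1, 6)                         # interior still swollen
})

test_that("degenerate fitting inputs are rejected", {
  p <- deswellParams(nElements = 10L)
  tr <- simulateDeswell(p, 900, seq(0, 900, length.out = 21))
  profs <- lapply(c(300, 600, 900), function(t) modelVelocityProfile(tr, t))
  th <- approx(tr@times, tr@thickness * 1e4, xout = c(300, 600, 900))$y
  expect_error(fitToDVI(profs[1:2], c(300, 600), th[1:2], template = p),
               ">= 3")
  expect_error(fitToDVI(profs, c(300, 600, 900), th, template = p,
                        bounds = list(kOverMu = c(2e-12, 1e-12),
                                      Lendo = c(1e-12, 1e-9),
                                      H0 = c(2, 8), Heq = c(1, 4))),
               "degenerate")
})
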