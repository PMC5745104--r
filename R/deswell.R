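# 1-D osmotic de-swelling model of the corneal stroma (CGS units).
#
# The stroma is nElements elements of equal dry thickness delta = D_dry/N;
# dry matrix and water both have density 1 g/cm^3, so an element of
# hydration H_i (wet/dry mass ratio) has wet thickness h_i = delta*(1+H_i).
# Fluid pressure in an element is minus its swelling pressure, water moves
# between neighbours by Darcy flow and leaves through the posterior
# (endothelial) membrane against the bath osmotic pressure.

#' Construct de-swelling model parameters
#'
#' Defaults are a fitted human-cornea parameter set in CGS units:
#' `C = 2.41e6` dyne/cm^2, `k/mu = 10e-12` cm^4/(s dyne), endothelial
#' `L = 179e-12` cm^3/(s dyne), initial hydration 7.6 de-swelling to an
#' equilibrium hydration of 2.44, sealed anterior boundary (intact
#' epithelium: osmotic flow through it is negligible), 50 elements. The dry
#' thickness default (120 um) puts the initial swollen thickness near 1 mm.
#'
#' @param C swelling-pressure constant (dyne/cm^2).
#' @param gamma swelling-pressure exponent of the default power law.
#' @param kOverMu stromal flow conductivity (cm^4/(s dyne)).
#' @param Lendo endothelial membrane hydraulic conductivity (cm^3/(s dyne)).
#' @param H0 initial hydration M_W/M_D.
#' @param Heq de-swollen equilibrium hydration (sets the bath pressure
#'   `piExt = swellingPressure(Heq, C, gamma)`).
#' @param anteriorBoundary `"sealed"`, `"membrane"` or `"open"`.
#' @param Lepi anterior membrane conductivity (only for `"membrane"`).
#' @param nElements number of equal-dry-thickness elements.
#' @param dryThickness total dry thickness (cm).
#' @return a [DeswellParams-class].
#' @export
deswellParams <- function(C = 2.41e6, gamma = 2, kOverMu = 10e-12,
                          Lendo = 179e-12, H0 = 7.6, Heq = 2.44,
                          anteriorBoundary = "sealed", Lepi = 0,
                          nElements = 50L, dryThickness = 0.012) {
  # Class= spelled out: a named C argument would otherwise partially match it
  new(Class = "DeswellParams", C = C, gamma = gamma, kOverMu = kOverMu,
      Lendo = Lendo, H0 = H0, Heq = Heq,
      piExt = swellingPressure(Heq, C, gamma),
      anteriorBoundary = anteriorBoundary, Lepi = Lepi,
      nElements = as.integer(nElements), dryThickness = dryThickness)
}

#' Swelling pressure law
#'
#' Monotone-decreasing power law \eqn{\Pi(H) = C H^{-\gamma}}: positive for
#' all H > 0, vanishing as the stroma swells to large hydration.
#'
#' @param H hydration M_W/M_D (> 0).
#' @param C pressure constant (dyne/cm^2).
#' @param gamma exponent (> 0).
#' @return swelling pressure (dyne/cm^2).
#' @export
swellingPressure <- function(H, C = 2.41e6, gamma = 2) {
  if (any(H <= 0)) stop("hydration must be > 0")
  C * H^(-gamma)
}

# boundary tags encoded for the compiled integrator
.boundaryCode <- function(params) {
  switch(params@anteriorBoundary, sealed = 0L, membrane = 1L, open = 2L)
}

# per-element hydration time-derivative and boundary fluxes (R reference
# implementation; the compiled integrator reproduces this arithmetic)
.deswellRates <- function(H, params) {
  N <- params@nElements
  delta <- params@dryThickness / N
  h <- delta * (1 + H)
  Pi <- swellingPressure(H, params@C, params@gamma)
  P <- -Pi
  q <- numeric(N - 1)
  dx <- (h[-N] + h[-1]) / 2
  q <- params@kOverMu * (P[-N] - P[-1]) / dx          # flux element i -> i+1
  jPost <- params@Lendo * (params@piExt - Pi[N])       # outward posterior
  jAnt <- switch(params@anteriorBoundary,
    sealed = 0,
    membrane = params@Lepi * (params@piExt - Pi[1]),
    open = params@kOverMu * (params@piExt - Pi[1]) / (h[1] / 2))
  dH <- numeric(N)
  dH[1] <- (-q[1] - jAnt) / delta
  if (N > 2) dH[2:(N - 1)] <- (q[1:(N - 2)] - q[2:(N - 1)]) / delta
  dH[N] <- (q[N - 1] - jPost) / delta
  list(dH = dH, jPost = jPost, jAnt = jAnt)
}

#' One explicit Euler step of the de-swelling model
#'
#' Advances the per-element hydration by `dt` seconds using Darcy fluxes
#' between neighbouring elements and membrane fluxes at the boundaries.
#' Water is conserved exactly: the change in total water column equals
#' minus the boundary outflow times `dt`.
#'
#' @param state a [ModelState-class].
#' @param params a [DeswellParams-class].
#' @param dt time step (s); must respect [stabilityDt()].
#' @return the advanced [ModelState-class].
#' @export
stepDeswell <- function(state, params, dt) {
  r <- .deswellRates(state@hydration, params)
  H <- state@hydration + dt * r$dH
  if (any(H < 0))
    stop("negative hydration after step: reduce dt below stabilityDt()")
  new("ModelState", hydration = H, time = state@time + dt)
}

#' Stability bound for the explicit Euler step
#'
#' Conservative diffusion-type bound
#' \eqn{dt \le s\,\min(\Delta x\,\delta / (2 (k/\mu) |\Pi'|),\;
#' \delta / (2 L |\Pi'|))} with \eqn{|\Pi'|} evaluated at the smallest
#' hydration the run can reach (slightly below `Heq`).
#'
#' @param params a [DeswellParams-class].
#' @param state optional current [ModelState-class] (tightens the bound to
#'   the current hydration range).
#' @param safety safety factor in (0, 1\].
#' @return maximum stable dt (s).
#' @export
stabilityDt <- function(params, state = NULL, safety = 0.5) {
  N <- params@nElements
  delta <- params@dryThickness / N
  hMin <- if (is.null(state)) min(params@Heq, params@H0) * 0.9
          else min(min(state@hydration), params@Heq) * 0.9
  dPiMax <- params@gamma * params@C * hMin^(-params@gamma - 1)
  dxMin <- delta * (1 + hMin)
  dtInt <- if (params@kOverMu > 0)
    dxMin * delta / (2 * params@kOverMu * dPiMax) else Inf
  Lmax <- max(params@Lendo,
              if (params@anteriorBoundary == "membrane") params@Lepi else 0)
  dtMem <- if (Lmax > 0) delta / (2 * Lmax * dPiMax) else Inf
  safety * min(dtInt, dtMem)
}

#' Simulate a de-swelling trajectory
#'
#' Integrates the model with fixed-step explicit Euler (step from
#' [stabilityDt()] unless overridden), sampling hydration profiles exactly
#' at `sampleTimes`. Element boundary depths are accumulated from the fixed
#' anterior face; boundary velocities are finite differences of those
#' depths between adjacent samples (central in the interior, one-sided at
#' the ends), i.e. velocities relative to the anterior reference, matching
#' the DVI reference convention for corneas with an intact epithelium.
#'
#' @param params a [DeswellParams-class].
#' @param tEnd end time (s).
#' @param sampleTimes sample times (s); default 41 evenly spaced including
#'   0 and `tEnd`.
#' @param dt Euler step override (s); `NULL` uses the stability bound.
#' @return a [ModelTrajectory-class].
#' @examples
#' p <- deswellParams(nElements = 10L)
#' tr <- simulateDeswell(p, tEnd = 600)
#' tr@thickness[1] * 1e4   # initial swollen thickness, um
#' @export
simulateDeswell <- function(params, tEnd, sampleTimes = NULL, dt = NULL) {
  if (is.null(sampleTimes)) sampleTimes <- seq(0, tEnd, length.out = 41)
  sampleTimes <- sort(unique(c(0, sampleTimes)))
  if (max(sampleTimes) > tEnd + 1e-9) stop("sampleTimes beyond tEnd")
  if (is.null(dt)) dt <- stabilityDt(params)
  N <- params@nElements
  delta <- params@dryThickness / N
  H <- rep(params@H0, N)
  res <- deswell_integrate_cpp(H, params@C, params@gamma, params@kOverMu,
                               params@Lendo, params@Lepi, params@piExt,
                               delta, dt, sampleTimes, .boundaryCode(params))
  Hs <- res$hydration                       # N x nSamples
  if (any(Hs < 0))
    stop("negative hydration during integration: reduce dt")
  nt <- length(sampleTimes)
  thick <- delta * (N + colSums(Hs))
  bDepth <- rbind(0, apply(delta * (1 + Hs), 2, cumsum))
  vel <- matrix(0, N + 1, nt)
  if (nt >= 2) {
    for (j in seq_len(nt)) {
      jm <- max(1L, j - 1L); jp <- min(nt, j + 1L)
      vel[, j] <- (bDepth[, jp] - bDepth[, jm]) /
                  (sampleTimes[jp] - sampleTimes[jm])
    }
  }
  new("ModelTrajectory", times = sampleTimes, hydration = Hs,
      thickness = thick, boundaryDepth = bDepth, velocity = vel,
      outflux = res$outflux, params = params)
}

#' Model velocity profile at a given time
#'
#' Re-expresses a trajectory's boundary velocities as a profile over
#' distance from the posterior (endothelial) face, in nm/s, with the
#' anterior face as the zero-velocity reference. Linear interpolation
#' between the two bracketing samples; extrapolation beyond the sampled
#' range is an error.
#'
#' @param trajectory a [ModelTrajectory-class].
#' @param time requested time (s), within the sampled range.
#' @return an [AxialVelocityProfile-class].
#' @export
modelVelocityProfile <- function(trajectory, time) {
  tt <- trajectory@times
  if (time < tt[1] - 1e-9 || time > tt[length(tt)] + 1e-9)
    stop("time outside trajectory samples")
  j <- findInterval(time, tt, all.inside = TRUE)
  w <- (time - tt[j]) / (tt[j + 1] - tt[j])
  depth <- (1 - w) * trajectory@boundaryDepth[, j] +
           w * trajectory@boundaryDepth[, j + 1]
  vel <- (1 - w) * trajectory@velocity[, j] + w * trajectory@velocity[, j + 1]
  distUm <- rev(max(depth) - depth) * 1e4
  velNm <- rev(vel) * 1e7
  ord <- order(distUm)
  new("AxialVelocityProfile", distanceUm = distUm[ord],
      meanVelocity = velNm[ord], nColumns = rep(1L, length(distUm)),
      fromInterface = "posterior")
}
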