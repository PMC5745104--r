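# Deterministic fitting of the de-swelling model constants to measured
# axial velocity profiles: coarse grid search followed by Nelder-Mead
# refinement (the reproducible replacement for manual fitting).

#' Fit de-swelling model constants to measured DVI profiles
#'
#' Recovers (k/mu, L, H0, Heq) by minimising the summed squared difference
#' between measured axial velocity profiles (distance from the endothelial
#' interface, nm/s) at three or more times and the model's velocity
#' profiles at those times, plus a weighted squared thickness mismatch.
#' A coarse grid over the bounds (log-spaced for the conductivities) is
#' followed by Nelder-Mead refinement from the best grid point. The model
#' start may optionally be offset in time relative to the first measurement
#' (`fitOffset`), reported as the fitted nuisance start time/thickness.
#'
#' @param profiles list of [AxialVelocityProfile-class] (from
#'   [axialProfile()] or [modelVelocityProfile()]), one per time.
#' @param timesS measurement times (s) on the model clock, same length as
#'   `profiles`, at least 3.
#' @param thicknessUm measured mean geometric thickness (um) at those times.
#' @param template a [DeswellParams-class] fixing C, gamma, the boundary
#'   tag, element count and dry thickness.
#' @param bounds named list with `kOverMu`, `Lendo`, `H0`, `Heq`, each
#'   `c(lower, upper)`.
#' @param gridN grid points per parameter for the coarse search.
#' @param thicknessWeight weight of the thickness residual
#'   ((nm/s)^2 per um^2).
#' @param fitOffset also fit a model start-time offset (s)?
#' @param offsetBounds bounds for the offset when fitted.
#' @param nSampleGrid number of internal trajectory samples.
#' @param dtSafety Euler-step safety factor used during fitting (the
#'   stability bound is conservative; accuracy is step-limited well below
#'   it).
#' @param control passed to [stats::optim()] Nelder-Mead.
#' @return list with `params` (fitted [DeswellParams-class]), `objective`,
#'   `offsetS`, `startThicknessUm`, `residuals` (list of per-time
#'   data.frames), `gridBest`, `convergence`.
#' @export
fitToDVI <- function(profiles, timesS, thicknessUm, template = deswellParams(),
                     bounds = list(kOverMu = c(0.3e-12, 29e-12),
                                   Lendo = c(5e-12, 500e-12),
                                   H0 = c(1.5, 8), Heq = c(1.5, 8)),
                     gridN = 4L, thicknessWeight = 10,
                     fitOffset = FALSE, offsetBounds = c(0, 1800),
                     nSampleGrid = 61L, dtSafety = 0.8, control = list()) {
  stopifnot(length(profiles) == length(timesS),
            length(thicknessUm) == length(timesS))
  if (length(profiles) < 3) stop("need profiles at >= 3 times")
  for (nm in c("kOverMu", "Lendo", "H0", "Heq")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] >= b[2] || any(b <= 0))
      stop(sprintf("degenerate bounds for %s", nm))
  }
  measGrids <- lapply(profiles, function(p) p@distanceUm)
  measVals <- lapply(profiles, function(p) p@meanVelocity)

  evalTheta <- function(kmu, L, H0, Heq, off) {
    if (H0 < Heq) return(Inf)
    p <- deswellParams(C = template@C, gamma = template@gamma,
                       kOverMu = kmu, Lendo = L, H0 = H0, Heq = Heq,
                       anteriorBoundary = template@anteriorBoundary,
                       Lepi = template@Lepi, nElements = template@nElements,
                       dryThickness = template@dryThickness)
    tEnd <- max(timesS) + off
    tr <- tryCatch(
      simulateDeswell(p, tEnd, seq(0, tEnd, length.out = nSampleGrid),
                      dt = stabilityDt(p, safety = dtSafety)),
      error = function(e) NULL)
    if (is.null(tr)) return(Inf)
    ss <- 0
    for (i in seq_along(timesS)) {
      mp <- modelVelocityProfile(tr, timesS[i] + off)
      mv <- stats::approx(mp@distanceUm, mp@meanVelocity,
                          xout = measGrids[[i]], rule = 2)$y
      ss <- ss + sum((mv - measVals[[i]])^2)
      tMod <- stats::approx(tr@times, tr@thickness * 1e4,
                            xout = timesS[i] + off, rule = 2)$y
      ss <- ss + thicknessWeight * (tMod - thicknessUm[i])^2
    }
    ss
  }

  gLog <- function(b, n) exp(seq(log(b[1]), log(b[2]), length.out = n))
  gLin <- function(b, n) seq(b[1], b[2], length.out = n)
  grid <- expand.grid(kmu = gLog(bounds$kOverMu, gridN),
                      L = gLog(bounds$Lendo, gridN),
                      H0 = gLin(bounds$H0, gridN),
                      Heq = gLin(bounds$Heq, gridN))
  offGrid <- if (fitOffset) gLin(offsetBounds, 3L) else 0
  best <- NULL; bestVal <- Inf
  for (off in offGrid) {
    vals <- vapply(seq_len(nrow(grid)), function(i)
      evalTheta(grid$kmu[i], grid$L[i], grid$H0[i], grid$Heq[i], off),
      numeric(1))
    i <- which.min(vals)
    if (vals[i] < bestVal) {
      bestVal <- vals[i]
      best <- c(log(grid$kmu[i]), log(grid$L[i]), grid$H0[i], grid$Heq[i],
                off)
    }
  }
  if (!is.finite(bestVal)) stop("no feasible parameter combination in bounds")

  loTh <- c(log(bounds$kOverMu[1]), log(bounds$Lendo[1]),
            bounds$H0[1], bounds$Heq[1],
            if (fitOffset) offsetBounds[1])
  hiTh <- c(log(bounds$kOverMu[2]), log(bounds$Lendo[2]),
            bounds$H0[2], bounds$Heq[2],
            if (fitOffset) offsetBounds[2])
  clampTheta <- function(th) pmin(pmax(th, loTh), hiTh)
  obj <- function(th) {
    tol <- 1e-8 * (abs(hiTh - loTh) + 1)
    if (any(th < loTh - tol) || any(th > hiTh + tol)) return(1e12)
    evalTheta(exp(th[1]), exp(th[2]), th[3], th[4],
              if (fitOffset) th[5] else 0)
  }
  th0 <- if (fitOffset) best else best[1:4]
  # pull a grid-corner start slightly into the interior so the initial
  # simplex does not straddle the out-of-bounds penalty
  th0 <- 0.95 * th0 + 0.05 * (loTh + hiTh) / 2
  ctrl <- utils::modifyList(list(maxit = 300L, reltol = 1e-8), control)
  opt <- stats::optim(th0, obj, method = "Nelder-Mead", control = ctrl)
  # one restart from the incumbent guards against premature simplex collapse
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead", control = ctrl)
  if (opt2$value < opt$value) opt <- opt2
  th <- clampTheta(opt$par)
  off <- if (fitOffset) th[5] else 0
  fitted <- deswellParams(C = template@C, gamma = template@gamma,
                          kOverMu = exp(th[1]), Lendo = exp(th[2]),
                          H0 = th[3], Heq = th[4],
                          anteriorBoundary = template@anteriorBoundary,
                          Lepi = template@Lepi,
                          nElements = template@nElements,
                          dryThickness = template@dryThickness)
  tEnd <- max(timesS) + off
  tr <- simulateDeswell(fitted, tEnd, seq(0, tEnd, length.out = nSampleGrid))
  residuals <- lapply(seq_along(timesS), function(i) {
    mp <- modelVelocityProfile(tr, timesS[i] + off)
    mv <- stats::approx(mp@distanceUm, mp@meanVelocity,
                        xout = measGrids[[i]], rule = 2)$y
    data.frame(distance_um = measGrids[[i]], measured = measVals[[i]],
               modelled = mv, residual = mv - measVals[[i]])
  })
  list(params = fitted, objective = opt$value, offsetS = off,
       startThicknessUm = tr@thickness[1] * 1e4, residuals = residuals,
       gridBest = bestVal, convergence = opt$convergence)
}
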