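# DVI core: reference-pixel selection, temporal phase unwrapping, phase-rate
# regression, velocity conversion, the full per-stack computation, axial
# averaging and noise-floor estimation.

#' Select the per-column reference pixel
#'
#' Returns the row of the strongest amplitude within `halfwidth` pixels of a
#' set point — the pixel whose phase anchors zero velocity for that A-scan.
#' Ties go to the smaller row.
#'
#' @param amplitudeColumn numeric amplitude values of one A-scan.
#' @param setRow set-point row.
#' @param halfwidth search half-width (pixels), default 10.
#' @return integer row index.
#' @export
selectReferencePixel <- function(amplitudeColumn, setRow, halfwidth = 10L) {
  n <- length(amplitudeColumn)
  lo <- max(1L, as.integer(round(setRow)) - as.integer(halfwidth))
  hi <- min(n, as.integer(round(setRow)) + as.integer(halfwidth))
  if (lo > hi || lo > n || hi < 1) stop("empty reference search window")
  lo + which.max(amplitudeColumn[lo:hi]) - 1L
}

#' Temporally unwrap a phase series
#'
#' Adjusts consecutive differences by multiples of 2*pi so every increment
#' lies in \[-pi, pi\]; the first element is unchanged.
#'
#' @param series wrapped phase values (rad), one per frame.
#' @return unwrapped series, same length.
#' @examples
#' temporalUnwrap(c(0, 2.5, -1.3))   # third element ~ 4.983
#' @export
temporalUnwrap <- function(series) {
  n <- length(series)
  if (n < 2) return(series)
  d <- diff(series)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(series[1], d))
}

# unwrap dim-3 (frame) increments of an [rows, cols, frames] phase array
.temporalUnwrapArray <- function(ph) {
  nf <- dim(ph)[3]
  out <- ph
  for (k in 2:nf) {
    d <- ph[, , k] - ph[, , k - 1]
    d <- d - 2 * pi * round(d / (2 * pi))
    out[, , k] <- out[, , k - 1] + d
  }
  out
}

#' Temporal phase rate by linear regression
#'
#' Ordinary least-squares slope of an unwrapped phase series against its
#' timestamps.
#'
#' @param series unwrapped phase values (rad).
#' @param timestamps frame times (s).
#' @return slope d(phi)/d(tau) in rad/s.
#' @export
phaseRate <- function(series, timestamps) {
  stopifnot(length(series) == length(timestamps), length(series) >= 2)
  tc <- timestamps - mean(timestamps)
  s2 <- sum(tc^2)
  if (s2 == 0) stop("all timestamps equal")
  sum(tc * series) / s2
}

#' Convert a phase rate to an axial velocity
#'
#' \eqn{v = (d\phi/d\tau) \lambda / (4 \pi n)}; the sign of the rate is
#' preserved.
#'
#' @param rate phase rate (rad/s).
#' @param wavelength centre wavelength (nm).
#' @param n medium refractive index.
#' @return velocity in nm/s.
#' @export
velocityFromPhaseRate <- function(rate, wavelength = 800, n = 1.37) {
  stopifnot(wavelength > 0, n > 0)
  rate * wavelength / (4 * pi * n)
}

#' Nyquist (aliasing) velocity cap
#'
#' The largest measurable axial velocity, corresponding to a phase step of
#' pi per inter-frame interval: \eqn{v_{max} = \lambda f / (4 n)}. For the
#' 800 nm, 2 Hz corneal configuration (n = 1.37) this is about 292 nm/s.
#'
#' @param object an [AcquisitionGeometry-class], or the wavelength (nm) when
#'   called with plain numbers.
#' @param n medium refractive index (numeric call).
#' @param frameRate frame rate in Hz (numeric call).
#' @param ... unused.
#' @return velocity cap in nm/s.
#' @examples
#' nyquistVelocity(800, n = 1.37, frameRate = 2)
#' @rdname nyquistVelocity
#' @export
setMethod("nyquistVelocity", "AcquisitionGeometry", function(object, ...) {
  object@wavelength * object@frameRate / (4 * object@groupIndex)
})

#' @rdname nyquistVelocity
setMethod("nyquistVelocity", "numeric", function(object, n = 1.37,
                                                 frameRate = 2, ...) {
  stopifnot(object > 0, n > 0, frameRate > 0)
  object * frameRate / (4 * n)
})

#' Measurement window of a stack
#'
#' Total time spanned by the frames of one DVI measurement,
#' `nFrames / frameRate` (10 frames at 2 Hz span 5 s) — small against the
#' de-swelling timescale, so one DVI image is quasi-instantaneous.
#'
#' @param object an [AcquisitionGeometry-class] or
#'   [ComplexFrameStack-class].
#' @param ... unused.
#' @return window length in seconds.
#' @rdname measurementWindow
#' @export
setMethod("measurementWindow", "AcquisitionGeometry", function(object, ...) {
  object@nFrames / object@frameRate
})

#' @rdname measurementWindow
setMethod("measurementWindow", "ComplexFrameStack", function(object, ...) {
  measurementWindow(object@geometry)
})

#' Convert an optical (in-air) length to a geometric length in the medium
#'
#' Divides by the group refractive index: 12 um axial resolution in air is
#' 12/1.37 ~ 8.8 um (9 um) in cornea; a 5.2 mm air range is 3.8 mm.
#'
#' @param length optical length (any unit).
#' @param n group refractive index.
#' @return geometric length in the medium, same unit.
#' @export
opticalToGeometric <- function(length, n = 1.37) {
  stopifnot(n > 0)
  length / n
}

#' DVI computation configuration
#'
#' @param refractiveIndex index used in the phase-to-velocity conversion
#'   (`NULL` = the stack geometry's group index; 1.37 for cornea).
#' @param boxcarSize odd boxcar size for the smoothed image (pixels).
#' @param referenceHalfwidth search half-width around the set point.
#' @param nyquistWarnFraction warn when |v| exceeds this fraction of the
#'   Nyquist cap.
#' @return named list of class `dviConfig`.
#' @export
dviConfig <- function(refractiveIndex = NULL, boxcarSize = 5L,
                      referenceHalfwidth = 10L, nyquistWarnFraction = 0.9) {
  structure(list(refractiveIndex = refractiveIndex,
                 boxcarSize = as.integer(boxcarSize),
                 referenceHalfwidth = as.integer(referenceHalfwidth),
                 nyquistWarnFraction = nyquistWarnFraction),
            class = "dviConfig")
}

#' Compute a deformation-velocity image from a complex frame stack
#'
#' Implements the four-step phase pipeline per A-scan: (1) choose the
#' reference pixel (strongest amplitude within the search window of the set
#' point — the epithelial interface for `with_epithelium` scenes, the
#' midpoint between anterior and posterior otherwise) and subtract its phase
#' from the whole A-scan in every frame, removing bulk motion; (2) subtract
#' each pixel's first-frame phase; (3) unwrap the referenced phase change
#' over the frames; (4) regress it against the timestamps and convert the
#' slope to nm/s via \eqn{v_r = (d(\phi_P-\phi_{RP})/d\tau)\,\lambda/4\pi n}.
#' The result is masked to the segmented cornea; boxcar smoothing is applied
#' to the masked image only and kept separately from the raw values used for
#' axial averaging.
#'
#' @param stack a [ComplexFrameStack-class] with >= 2 frames.
#' @param interfaces a [CornealInterfaces-class] segmented on frame 1.
#' @param config a [dviConfig()].
#' @return a [DeformationVelocityImage-class].
#' @export
computeDVI <- function(stack, interfaces, config = dviConfig()) {
  stopifnot(is(stack, "ComplexFrameStack"), is(interfaces, "CornealInterfaces"))
  d <- dim(stack@frames)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  if (nf < 2) stop("need at least 2 frames")
  geom <- stack@geometry
  nIdx <- if (is.null(config$refractiveIndex)) geom@groupIndex
          else config$refractiveIndex
  ant <- interfaces@anterior@rows
  post <- interfaces@posterior@rows
  if (interfaces@variant == "with_epithelium" &&
      !is.null(interfaces@auxiliary$epithelial)) {
    setRows <- interfaces@auxiliary$epithelial@rows
    rule <- "epithelial_interface"
  } else {
    setRows <- as.integer(round((ant + post) / 2))
    rule <- "mid_depth"
  }
  amp0 <- Mod(stack@frames[, , 1])
  refRows <- vapply(seq_len(nc), function(c)
    selectReferencePixel(amp0[, c], setRows[c], config$referenceHalfwidth),
    integer(1))

  ph <- Arg(stack@frames)
  # (1) subtract the reference-pixel phase per column, per frame
  for (k in seq_len(nf)) {
    refPhase <- ph[, , k][cbind(refRows, seq_len(nc))]
    ph[, , k] <- wrapPhase(sweep(ph[, , k], 2, refPhase, "-"))
  }
  # (2) subtract the first-frame value per pixel
  first <- ph[, , 1]
  for (k in seq_len(nf)) ph[, , k] <- wrapPhase(ph[, , k] - first)
  # (3) temporal unwrap, (4) OLS slope against the timestamps
  ph <- .temporalUnwrapArray(ph)
  tc <- stack@timestamps - mean(stack@timestamps)
  s2 <- sum(tc^2)
  if (s2 == 0) stop("all timestamps equal")
  dim(ph) <- c(nr * nc, nf)
  slope <- as.vector(ph %*% (tc / s2))
  v <- matrix(velocityFromPhaseRate(slope, geom@wavelength, nIdx), nr, nc)

  mask <- matrix(FALSE, nr, nc)
  for (c in seq_len(nc)) mask[ant[c]:post[c], c] <- TRUE
  mask <- mask & amp0 > 0   # a zero-signal pixel has no defined phase
  vmax <- nyquistVelocity(geom)
  if (max(abs(v[mask])) > config$nyquistWarnFraction * vmax)
    warning(sprintf("velocities approach the Nyquist cap (%.0f nm/s); aliasing possible",
                    vmax))
  raw <- v
  raw[!mask] <- NA_real_
  sm <- boxcarFilter2(raw, config$boxcarSize)
  sm[!mask] <- NA_real_
  new("DeformationVelocityImage", velocity = raw, smoothed = sm, mask = mask,
      referenceRows = refRows, setPointRule = rule,
      refractiveIndex = nIdx, boxcarSize = config$boxcarSize,
      geometry = geom)
}

#' Axial-averaged velocity profile from a named interface
#'
#' For each integer pixel distance d from the chosen interface, averages the
#' raw (unsmoothed) velocity over all columns that have a valid corneal
#' pixel at that distance; distances are converted to um in the medium.
#'
#' @param dvi a [DeformationVelocityImage-class].
#' @param interfaces the [CornealInterfaces-class] used for the DVI.
#' @param fromInterface `"posterior"` (endothelial, default) or
#'   `"anterior"`.
#' @return an [AxialVelocityProfile-class].
#' @export
axialProfile <- function(dvi, interfaces,
                         fromInterface = c("posterior", "anterior")) {
  fromInterface <- match.arg(fromInterface)
  if (!any(dvi@mask)) stop("empty mask")
  ant <- interfaces@anterior@rows
  post <- interfaces@posterior@rows
  nc <- ncol(dvi@velocity)
  maxD <- max(post - ant)
  pitchMed <- dvi@geometry@axialPitchAir / dvi@geometry@groupIndex
  meanV <- numeric(maxD + 1L)
  nCols <- integer(maxD + 1L)
  for (d in 0:maxD) {
    rows <- if (fromInterface == "posterior") post - d else ant + d
    ok <- rows >= ant & rows <= post
    vals <- dvi@velocity[cbind(rows[ok], which(ok))]
    vals <- vals[!is.na(vals)]
    nCols[d + 1L] <- length(vals)
    meanV[d + 1L] <- if (length(vals)) mean(vals) else NA_real_
  }
  keep <- nCols > 0
  new("AxialVelocityProfile", distanceUm = (0:maxD)[keep] * pitchMed,
      meanVelocity = meanV[keep], nColumns = nCols[keep],
      fromInterface = fromInterface)
}

#' Noise floor of a deformation-velocity representation
#'
#' Sample standard deviation over a region, for the raw pixel values, the
#' boxcar-smoothed image, or the axial-averaged profile. Applied to a stack
#' of an equilibrated (static) sample this estimates the minimum detectable
#' velocity of each representation; spatial averaging lowers the floor
#' roughly as the square root of the number of pixels averaged.
#'
#' @param dvi a [DeformationVelocityImage-class].
#' @param mode `"raw"`, `"smoothed"` or `"axial_averaged"`.
#' @param interfaces required for `"axial_averaged"`.
#' @param region optional logical matrix restricting the estimate.
#' @param minPixels minimum number of valid pixels required.
#' @return standard deviation in nm/s.
#' @export
noiseFloor <- function(dvi, mode = c("raw", "smoothed", "axial_averaged"),
                       interfaces = NULL, region = NULL, minPixels = 100L) {
  mode <- match.arg(mode)
  sel <- dvi@mask
  if (!is.null(region)) sel <- sel & region
  if (sum(sel) < minPixels)
    stop(sprintf("region too small: %d < %d valid pixels", sum(sel), minPixels))
  if (mode == "raw") return(stats::sd(dvi@velocity[sel], na.rm = TRUE))
  if (mode == "smoothed") return(stats::sd(dvi@smoothed[sel], na.rm = TRUE))
  if (is.null(interfaces)) stop("axial_averaged mode needs the interfaces")
  prof <- axialProfile(dvi, interfaces)
  # distances averaged over few columns are ill-determined; estimate the
  # floor from the well-supported part of the profile
  ok <- prof@nColumns >= max(prof@nColumns) / 2
  stats::sd(prof@meanVelocity[ok])
}
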