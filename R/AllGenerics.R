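# Generics, accessors and show methods.

#' @rdname nyquistVelocity
#' @export
setGeneric("nyquistVelocity", function(object, ...) standardGeneric("nyquistVelocity"))

#' @rdname measurementWindow
#' @export
setGeneric("measurementWindow", function(object, ...) standardGeneric("measurementWindow"))

#' Amplitude image of a stack frame
#'
#' @param object a [ComplexFrameStack-class] or [ScenePhantom-class].
#' @param frame frame index (stacks only).
#' @return the amplitude (modulus) matrix.
#' @export
setGeneric("amplitudeImage", function(object, frame = 1L) standardGeneric("amplitudeImage"))

#' @rdname amplitudeImage
setMethod("amplitudeImage", "ComplexFrameStack", function(object, frame = 1L) {
  Mod(object@frames[, , frame])
})

#' @rdname amplitudeImage
setMethod("amplitudeImage", "ScenePhantom", function(object, frame = 1L) {
  object@amplitude
})

#' Frame timestamps of a geometry or stack
#'
#' @param object an [AcquisitionGeometry-class] or [ComplexFrameStack-class].
#' @return numeric vector of frame times (s).
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname frameTimes
setMethod("frameTimes", "AcquisitionGeometry", function(object) {
  (seq_len(object@nFrames) - 1) / object@frameRate
})

#' @rdname frameTimes
setMethod("frameTimes", "ComplexFrameStack", function(object) object@timestamps)

#' Interface path accessors
#'
#' `anteriorPath()`/`posteriorPath()` return the per-column row indices of
#' the segmented anterior/posterior corneal interface; `pathRows()` those of
#' a single [InterfacePath-class].
#'
#' @param object a [CornealInterfaces-class] (or [InterfacePath-class]).
#' @return integer vector of row indices, one per column.
#' @export
setGeneric("anteriorPath", function(object) standardGeneric("anteriorPath"))

#' @rdname anteriorPath
setMethod("anteriorPath", "CornealInterfaces", function(object) object@anterior@rows)

#' @rdname anteriorPath
#' @export
setGeneric("posteriorPath", function(object) standardGeneric("posteriorPath"))

#' @rdname anteriorPath
setMethod("posteriorPath", "CornealInterfaces", function(object) object@posterior@rows)

#' @rdname anteriorPath
#' @export
setGeneric("pathRows", function(object) standardGeneric("pathRows"))

#' @rdname anteriorPath
setMethod("pathRows", "InterfacePath", function(object) object@rows)

#' Velocity matrix of a DVI image
#'
#' @param object a [DeformationVelocityImage-class].
#' @param smoothed return the boxcar-smoothed version?
#' @return velocity matrix in nm/s (`NA` outside the cornea mask).
#' @export
setGeneric("velocityImage", function(object, smoothed = FALSE) standardGeneric("velocityImage"))

#' @rdname velocityImage
setMethod("velocityImage", "DeformationVelocityImage", function(object, smoothed = FALSE) {
  if (smoothed) object@smoothed else object@velocity
})

#' @rdname velocityImage
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname velocityImage
setMethod("validMask", "DeformationVelocityImage", function(object) object@mask)

#' @rdname velocityImage
#' @export
setGeneric("referenceRows", function(object) standardGeneric("referenceRows"))

#' @rdname velocityImage
setMethod("referenceRows", "DeformationVelocityImage", function(object) object@referenceRows)

## data.frame views ----------------------------------------------------------

#' @export
#' @method as.data.frame ThicknessSeries
as.data.frame.ThicknessSeries <- function(x, ...) {
  data.frame(time_min = x@timeMin, mean_thickness_um = x@meanThicknessUm,
             sd_um = x@sdUm, n_columns = x@nColumns)
}
setMethod("as.data.frame", "ThicknessSeries", as.data.frame.ThicknessSeries)

#' @export
#' @method as.data.frame AxialVelocityProfile
as.data.frame.AxialVelocityProfile <- function(x, ...) {
  data.frame(distance_um = x@distanceUm, mean_velocity_nm_s = x@meanVelocity,
             n_columns = x@nColumns)
}
setMethod("as.data.frame", "AxialVelocityProfile", as.data.frame.AxialVelocityProfile)

#' @export
#' @method as.data.frame ModelTrajectory
as.data.frame.ModelTrajectory <- function(x, ...) {
  data.frame(time_s = x@times, thickness_um = x@thickness * 1e4)
}
setMethod("as.data.frame", "ModelTrajectory", as.data.frame.ModelTrajectory)

## show methods ---------------------------------------------------------------

setMethod("show", "AcquisitionGeometry", function(object) {
  cat(sprintf(paste0("AcquisitionGeometry: %g nm, n_G = %g, %g Hz, ",
                     "%g um/px axial (air), %d frames\n"),
              object@wavelength, object@groupIndex, object@frameRate,
              object@axialPitchAir, object@nFrames))
})

setMethod("show", "ComplexFrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ComplexFrameStack: %d x %d pixels, %d frames over %.3g s%s\n",
              d[1], d[2], d[3], diff(range(object@timestamps)),
              if (length(object@truth)) " (simulated, with truth)" else ""))
})

setMethod("show", "ScenePhantom", function(object) {
  cat(sprintf("ScenePhantom: %d x %d, SNR %.3g, %s epithelium, seed %d\n",
              nrow(object@amplitude), ncol(object@amplitude), object@snr,
              if (isTRUE(object@truth$hasEpithelium)) "with" else "without",
              object@seed))
})

setMethod("show", "CornealInterfaces", function(object) {
  cat(sprintf(paste0("CornealInterfaces (%s): %d columns, anterior rows ",
                     "%d-%d, posterior rows %d-%d, %d auxiliary path(s)\n"),
              object@variant, length(object@anterior@rows),
              min(object@anterior@rows), max(object@anterior@rows),
              min(object@posterior@rows), max(object@posterior@rows),
              length(object@auxiliary)))
})

setMethod("show", "DeformationVelocityImage", function(object) {
  v <- object@velocity[object@mask]
  cat(sprintf(paste0("DeformationVelocityImage: %d x %d, %d masked pixels, ",
                     "v_r in [%.3g, %.3g] nm/s (raw), n = %g\n"),
              nrow(object@velocity), ncol(object@velocity), sum(object@mask),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              object@refractiveIndex))
})

setMethod("show", "ThicknessSeries", function(object) {
  cat(sprintf("ThicknessSeries: %d time points (%d gaps), %.4g-%.4g um\n",
              length(object@timeMin), sum(is.na(object@meanThicknessUm)),
              min(object@meanThicknessUm, na.rm = TRUE),
              max(object@meanThicknessUm, na.rm = TRUE)))
})

setMethod("show", "DeswellParams", function(object) {
  cat(sprintf(paste0("DeswellParams (CGS): C = %.3g, gamma = %g, ",
                     "k/mu = %.3g, L = %.3g, H0 = %.3g, Heq = %.3g,\n",
                     "  anterior %s, N = %d, D_dry = %.3g cm\n"),
              object@C, object@gamma, object@kOverMu, object@Lendo,
              object@H0, object@Heq, object@anteriorBoundary,
              object@nElements, object@dryThickness))
})

setMethod("show", "ModelTrajectory", function(object) {
  cat(sprintf(paste0("ModelTrajectory: %d samples over %.4g s, thickness ",
                     "%.4g -> %.4g um\n"),
              length(object@times), max(object@times),
              object@thickness[1] * 1e4,
              object@thickness[length(object@thickness)] * 1e4))
})
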