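# Central S4 data containers shared by all stages.

#' Acquisition geometry of a Fourier-domain OCT B-scan stack
#'
#' Holds the instrument constants needed to convert pixel indices and phases
#' to physical units: centre wavelength (nm), medium group refractive index
#' \eqn{n_G}, frame rate (Hz), axial pixel pitch in air (um/pixel), lateral
#' pixel pitch (um/pixel) and the number of frames per measurement.
#'
#' The axial coordinate convention used everywhere in the package is:
#' row 1 is the shallowest depth, depth increases with row index, and axial
#' velocities are positive toward larger depth.
#'
#' @slot wavelength centre wavelength (nm).
#' @slot groupIndex group refractive index of the medium (1.37 for cornea).
#' @slot frameRate frame rate (Hz).
#' @slot axialPitchAir axial pixel pitch in air (um/pixel).
#' @slot lateralPitch lateral pixel pitch (um/pixel).
#' @slot nFrames number of frames per stack.
#' @export
setClass("AcquisitionGeometry",
  representation(wavelength = "numeric", groupIndex = "numeric",
                 frameRate = "numeric", axialPitchAir = "numeric",
                 lateralPitch = "numeric", nFrames = "integer"),
  validity = function(object) {
    v <- c(object@wavelength, object@groupIndex, object@frameRate,
           object@axialPitchAir, object@lateralPitch, object@nFrames)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all geometry fields must be finite and strictly positive")
    TRUE
  })

#' Construct an AcquisitionGeometry
#'
#' Defaults describe a line-field spectral-domain OCT system imaging cornea:
#' 800 nm centre wavelength, group index 1.37, 2 Hz frame rate, 5.2 um/pixel
#' axial pitch in air and 10 frames per measurement (a 5 s window).
#'
#' @param wavelength centre wavelength (nm).
#' @param groupIndex medium group refractive index.
#' @param frameRate frame rate (Hz).
#' @param axialPitchAir axial pixel pitch in air (um/pixel).
#' @param lateralPitch lateral pixel pitch (um/pixel).
#' @param nFrames frames per stack.
#' @return an [AcquisitionGeometry-class] object.
#' @examples
#' geom <- AcquisitionGeometry()
#' nyquistVelocity(geom)
#' @export
AcquisitionGeometry <- function(wavelength = 800, groupIndex = 1.37,
                                frameRate = 2, axialPitchAir = 5.2,
                                lateralPitch = 15, nFrames = 10L) {
  new("AcquisitionGeometry", wavelength = wavelength, groupIndex = groupIndex,
      frameRate = frameRate, axialPitchAir = axialPitchAir,
      lateralPitch = lateralPitch, nFrames = as.integer(nFrames))
}

#' Ground-truth deformation-velocity field
#'
#' A prescribed axial velocity field \eqn{v(z, x, t)} (nm/s; positive toward
#' larger depth) plus a uniform bulk-motion velocity \eqn{v_b(t)} applied to
#' every pixel. Depth `z` and lateral position `x` are geometric coordinates
#' in um (rows converted through the axial pitch and group index), `t` is in
#' seconds.
#'
#' @slot kind one of `"uniform_strain"`, `"exponential_front"`,
#'   `"model_trajectory"`, `"rigid"`, `"static"`.
#' @slot velocityFun `function(z_um, x_um, t_s)` returning nm/s, vectorised
#'   over `z_um`/`x_um`.
#' @slot bulkFun `function(t_s)` returning the bulk velocity (nm/s).
#' @slot params the parameters the field was built from.
#' @export
setClass("DeformationField",
  representation(kind = "character", velocityFun = "function",
                 bulkFun = "function", params = "list"),
  validity = function(object) {
    kinds <- c("uniform_strain", "exponential_front", "model_trajectory",
               "rigid", "static")
    if (!(object@kind %in% kinds))
      return(sprintf("unknown field kind '%s'", object@kind))
    TRUE
  })

#' Synthetic corneal scene phantom
#'
#' Static amplitude image of a layered cornea suspended in a vial (bright
#' container-wall lines, speckled stroma, optional scattering epithelial
#' band) together with the exact interface truth rows per column. Truth rows
#' are stored at sub-pixel (floating point) precision.
#'
#' @slot amplitude mean backscatter amplitude image (rows x cols, >= 0).
#' @slot truth list with numeric vectors `anterior`, `posterior`, optional
#'   `epithelial`, and `walls` (list of vectors), all of length ncol.
#' @slot snr amplitude signal-to-noise ratio of the stroma.
#' @slot seed speckle realisation seed.
#' @slot layout the layout parameters the scene was built from.
#' @export
setClass("ScenePhantom",
  representation(amplitude = "matrix", truth = "list", snr = "numeric",
                 seed = "integer", layout = "list"),
  validity = function(object) {
    if (any(object@amplitude < 0)) return("amplitude must be >= 0")
    tr <- object@truth
    if (is.null(tr$anterior) || is.null(tr$posterior))
      return("truth must contain anterior and posterior rows")
    if (!all(tr$anterior < tr$posterior))
      return("anterior row must be above posterior row for every column")
    TRUE
  })

#' Time-ordered stack of complex OCT B-scans
#'
#' The raw object DVI operates on: a complex array (depth x lateral x frame)
#' whose per-pixel argument is the Fourier phase, plus frame timestamps and
#' acquisition metadata. Stacks rendered by the simulator carry their scene
#' and field ground truth in `truth`.
#'
#' @slot frames complex array `[rows, cols, frames]`.
#' @slot timestamps frame times (s), strictly increasing.
#' @slot geometry an [AcquisitionGeometry-class].
#' @slot acquiredAt acquisition time since solution transfer (min; `NA` if
#'   not part of a timed series).
#' @slot truth optional list (`scene`, `field`, `t0`) for simulated stacks.
#' @export
setClass("ComplexFrameStack",
  representation(frames = "array", timestamps = "numeric",
                 geometry = "AcquisitionGeometry", acquiredAt = "numeric",
                 truth = "list"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3) return("frames must be a 3-D array")
    if (!is.complex(object@frames)) return("frames must be complex")
    if (length(object@timestamps) != d[3])
      return("one timestamp per frame required")
    if (d[3] > 1 && any(diff(object@timestamps) <= 0))
      return("timestamps must be strictly increasing")
    TRUE
  })

#' Per-pixel energy map for graph-search segmentation
#'
#' @slot energy non-negative finite cost matrix, same shape as source image.
#' @slot kind `"inverted_amplitude"` or `"inverted_vertical_gradient"`.
#' @slot medianSize median pre-filter size used.
#' @slot boxcarSize boxcar post-smoothing size used.
#' @export
setClass("EnergyMap",
  representation(energy = "matrix", kind = "character",
                 medianSize = "integer", boxcarSize = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@energy))) return("energy must be finite")
    if (any(object@energy < 0)) return("energy must be non-negative")
    if (!(object@kind %in% c("inverted_amplitude", "inverted_vertical_gradient")))
      return("unknown energy kind")
    TRUE
  })

#' A left-to-right minimum-energy interface path
#'
#' @slot rows integer row index per image column.
#' @slot label one of `"vial_wall"`, `"epithelial"`, `"anterior"`,
#'   `"posterior"`, `"path"`.
#' @slot stepBound per-column vertical step bound the path satisfies.
#' @export
setClass("InterfacePath",
  representation(rows = "integer", label = "character", stepBound = "integer"),
  validity = function(object) {
    if (length(object@rows) < 1) return("empty path")
    if (any(object@rows < 1)) return("rows must be >= 1")
    if (length(object@rows) > 1 &&
        any(abs(diff(object@rows)) > object@stepBound))
      return("path violates its step bound")
    TRUE
  })

#' Segmented corneal interfaces of one B-scan
#'
#' @slot anterior,posterior [InterfacePath-class] objects (posterior strictly
#'   below anterior in every column).
#' @slot auxiliary named list of further paths (container walls, epithelial
#'   layer).
#' @slot variant `"with_epithelium"` or `"without_epithelium"`.
#' @slot imageId identifier of the segmented image.
#' @export
setClass("CornealInterfaces",
  representation(anterior = "InterfacePath", posterior = "InterfacePath",
                 auxiliary = "list", variant = "character",
                 imageId = "character"),
  validity = function(object) {
    a <- object@anterior@rows; p <- object@posterior@rows
    if (length(a) != length(p)) return("anterior/posterior length mismatch")
    if (!all(a < p)) return("anterior must lie above posterior in every column")
    TRUE
  })

#' Deformation-velocity image
#'
#' Per-pixel relative axial velocity (nm/s, medium-corrected) inside the
#' segmented cornea. `velocity` holds the raw (unsmoothed) values used for
#' axial averaging; `smoothed` the boxcar-smoothed display version. Pixels
#' outside the validity mask are `NA`.
#'
#' @slot velocity raw velocity matrix (nm/s, `NA` outside mask).
#' @slot smoothed boxcar-smoothed velocity matrix.
#' @slot mask logical validity mask (segmented cornea).
#' @slot referenceRows per-column reference pixel row (velocity is relative
#'   to this depth; ~0 there by construction).
#' @slot setPointRule `"epithelial_interface"` or `"mid_depth"`.
#' @slot refractiveIndex index used in the phase-to-velocity conversion.
#' @slot boxcarSize smoothing window recorded.
#' @slot geometry acquisition geometry of the source stack.
#' @export
setClass("DeformationVelocityImage",
  representation(velocity = "matrix", smoothed = "matrix", mask = "matrix",
                 referenceRows = "integer", setPointRule = "character",
                 refractiveIndex = "numeric", boxcarSize = "integer",
                 geometry = "AcquisitionGeometry"),
  validity = function(object) {
    if (!identical(dim(object@velocity), dim(object@mask)))
      return("velocity/mask shape mismatch")
    if (any(!is.na(object@velocity[!object@mask])))
      return("pixels outside the mask must carry no value")
    TRUE
  })

#' Axial-averaged velocity profile
#'
#' Mean relative axial velocity as a function of distance from a named
#' interface, averaged over all columns with a valid pixel at that distance.
#'
#' @slot distanceUm distance from the interface (um, in medium), monotone.
#' @slot meanVelocity mean velocity (nm/s) at each distance.
#' @slot nColumns number of columns averaged at each distance.
#' @slot fromInterface `"posterior"` or `"anterior"`.
#' @export
setClass("AxialVelocityProfile",
  representation(distanceUm = "numeric", meanVelocity = "numeric",
                 nColumns = "integer", fromInterface = "character"),
  validity = function(object) {
    if (length(object@distanceUm) != length(object@meanVelocity))
      return("grid/profile length mismatch")
    if (is.unsorted(object@distanceUm, strictly = TRUE))
      return("distance grid must be strictly increasing")
    if (any(!is.finite(object@meanVelocity)))
      return("profile must be finite")
    TRUE
  })

#' Corneal thickness time series
#'
#' Mean geometric (medium-corrected) thickness versus time since solution
#' transfer. Failed time points are recorded as `NA` gaps, not dropped.
#'
#' @slot timeMin time since transfer (min), strictly increasing.
#' @slot meanThicknessUm mean geometric thickness (um; `NA` = gap).
#' @slot sdUm per-column thickness spread (um).
#' @slot nColumns columns averaged per time point.
#' @slot groupIndex group refractive index used for the correction.
#' @export
setClass("ThicknessSeries",
  representation(timeMin = "numeric", meanThicknessUm = "numeric",
                 sdUm = "numeric", nColumns = "integer",
                 groupIndex = "numeric"),
  validity = function(object) {
    if (length(object@timeMin) > 1 && any(diff(object@timeMin) <= 0))
      return("times must be strictly increasing")
    ok <- !is.na(object@meanThicknessUm)
    if (any(object@meanThicknessUm[ok] <= 0))
      return("thickness must be > 0")
    TRUE
  })

#' Parameters of the 1-D osmotic de-swelling model
#'
#' CGS units throughout. The stroma is divided into `nElements` elements of
#' equal dry thickness; hydration H = M_W/M_D is the state variable, the
#' swelling pressure law is \eqn{\Pi(H) = C H^{-\gamma}} by default, water
#' moves internally by Darcy flow (conductivity k/mu) and leaves through the
#' posterior (endothelial) membrane with hydraulic conductivity L against the
#' bath osmotic pressure \eqn{\pi_{ext} = \Pi(H_{eq})}.
#'
#' @slot C swelling-pressure constant (dyne/cm^2).
#' @slot gamma swelling-pressure exponent (dimensionless).
#' @slot kOverMu stromal flow conductivity k/mu (cm^4/(s dyne)).
#' @slot Lendo endothelial membrane hydraulic conductivity (cm^3/(s dyne)).
#' @slot H0 initial hydration M_W/M_D.
#' @slot Heq de-swollen equilibrium hydration (sets the bath pressure).
#' @slot piExt bath osmotic pressure (dyne/cm^2), derived from `Heq`.
#' @slot anteriorBoundary `"sealed"` (intact epithelium), `"membrane"`, or
#'   `"open"`.
#' @slot Lepi anterior membrane conductivity when `anteriorBoundary ==
#'   "membrane"`.
#' @slot nElements number of model elements.
#' @slot dryThickness total dry thickness D_dry (cm).
#' @export
setClass("DeswellParams",
  representation(C = "numeric", gamma = "numeric", kOverMu = "numeric",
                 Lendo = "numeric", H0 = "numeric", Heq = "numeric",
                 piExt = "numeric", anteriorBoundary = "character",
                 Lepi = "numeric", nElements = "integer",
                 dryThickness = "numeric"),
  validity = function(object) {
    if (object@kOverMu < 0 || object@Lendo < 0 || object@Lepi < 0)
      return("conductivities must be >= 0")
    if (object@Heq < 0) return("Heq must be >= 0")
    if (object@H0 < object@Heq) return("H0 must be >= Heq")
    if (object@nElements < 2) return("need at least 2 elements")
    if (object@dryThickness <= 0) return("dry thickness must be > 0")
    if (!(object@anteriorBoundary %in% c("sealed", "membrane", "open")))
      return("unknown anterior boundary tag")
    TRUE
  })

#' Per-element state of the de-swelling model
#'
#' @slot hydration hydration H_i per element (anterior = element 1).
#' @slot time model time (s).
#' @export
setClass("ModelState",
  representation(hydration = "numeric", time = "numeric"),
  validity = function(object) {
    if (any(object@hydration < 0)) return("hydration must be >= 0")
    TRUE
  })

#' Simulated de-swelling trajectory
#'
#' Sampled states of [simulateDeswell()]: per-sample hydration profiles,
#' total thickness, element boundary depths measured from the (fixed)
#' anterior face, and the boundary velocity profiles obtained by finite
#' differences of cumulative thickness between adjacent samples. `outflux`
#' records the cumulative water volume per unit area that has left through
#' each boundary, for conservation bookkeeping.
#'
#' @slot times sample times (s).
#' @slot hydration matrix `[nElements, nTimes]`.
#' @slot thickness total wet thickness (cm) per sample.
#' @slot boundaryDepth matrix `[nElements + 1, nTimes]` of interface depths
#'   from the anterior face (cm); row 1 is the anterior face itself (all 0).
#' @slot velocity matrix `[nElements + 1, nTimes]` of interface velocities
#'   (cm/s) relative to the anterior face.
#' @slot outflux matrix `[2, nTimes]`: cumulative posterior and anterior
#'   boundary outflow (cm^3/cm^2).
#' @slot params the generating [DeswellParams-class].
#' @export
setClass("ModelTrajectory",
  representation(times = "numeric", hydration = "matrix",
                 thickness = "numeric", boundaryDepth = "matrix",
                 velocity = "matrix", outflux = "matrix",
                 params = "DeswellParams"),
  validity = function(object) {
    if (length(object@times) != length(object@thickness))
      return("times/thickness length mismatch")
    if (any(object@thickness <= object@params@dryThickness))
      return("wet thickness must exceed dry thickness")
    TRUE
  })
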