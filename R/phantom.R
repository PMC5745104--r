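# Synthetic phantom: layered corneal scenes in a vial, prescribed
# deformation-velocity fields, and rendering to complex B-scan stacks whose
# Fourier phase evolves as 4*pi*n_G*z(t)/lambda.

.defaultLayout <- function() {
  list(nrow = 420L, ncol = 120L,
       wallRows = c(25, 400),        # container glass lines
       anteriorRow = 70,             # anterior interface at centre column
       thicknessPx = 230,            # corneal thickness in axial pixels
       curvaturePx = 8,              # sag of the anterior path at the edges
       posteriorCurvaturePx = NULL,  # defaults to curvaturePx
       epithelium = TRUE,
       epiThicknessPx = 6,
       lineAmplitude = 6,            # specular interface reflections
       wallAmplitude = 8,
       wallThicknessPx = 3,          # glass reflections are a few px thick
       epiAmplitude = 2.5,           # scattering epithelial band
       wallTiltPx = 2)
}

#' Build a synthetic corneal scene in a vial
#'
#' Constructs the static amplitude image of a swollen cornea suspended in a
#' viewing vial, as seen in a structural OCT B-scan: two thin bright
#' container-wall lines, a speckled scattering stroma bounded by curved
#' anterior/posterior interfaces carrying specular reflection lines, an
#' optional brighter scattering epithelial band below the anterior surface,
#' and near-zero amplitude elsewhere. Stromal speckle is drawn as the
#' magnitude of a unit-power complex Gaussian (Rayleigh amplitude). Interface
#' truth rows are stored at sub-pixel precision and define the scene's
#' segmentation ground truth.
#'
#' @param geometry an [AcquisitionGeometry-class] (recorded with the scene).
#' @param layout named list overriding the default layout; see Details.
#' @param snr stromal amplitude signal-to-noise ratio applied when the scene
#'   is rendered to frames (`Inf` = noiseless rendering).
#' @param seed integer speckle realisation seed; identical seeds give
#'   bit-identical scenes.
#' @details Layout fields: `nrow`, `ncol` (image size), `wallRows` (container
#'   wall rows), `anteriorRow` + `curvaturePx` (anterior path
#'   `a(c) = anteriorRow + curvaturePx * u^2` with `u` in \[-1, 1\] across
#'   columns), `thicknessPx` (+ optional `posteriorCurvaturePx`),
#'   `epithelium`/`epiThicknessPx`/`epiAmplitude`, `lineAmplitude`,
#'   `wallAmplitude`, `wallTiltPx`.
#' @return a [ScenePhantom-class].
#' @examples
#' sc <- makeCornealScene(AcquisitionGeometry(), snr = 20, seed = 1)
#' range(sc@truth$anterior)
#' @export
makeCornealScene <- function(geometry = AcquisitionGeometry(),
                             layout = list(), snr = 20, seed = 1L) {
  lay <- utils::modifyList(.defaultLayout(), layout)
  if (is.null(lay$posteriorCurvaturePx)) lay$posteriorCurvaturePx <- lay$curvaturePx
  if (!is.finite(snr) && !is.infinite(snr)) stop("snr must be numeric")
  if (snr <= 0) stop("snr must be > 0")
  nr <- as.integer(lay$nrow); nc <- as.integer(lay$ncol)
  u <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2)   # in [-1, 1]
  anterior <- lay$anteriorRow + lay$curvaturePx * u^2
  posterior <- lay$anteriorRow + lay$thicknessPx + lay$posteriorCurvaturePx * u^2
  walls <- lapply(lay$wallRows, function(w) w + lay$wallTiltPx * u)
  allRows <- c(anterior, posterior, unlist(walls))
  if (any(allRows < 2) || any(allRows > nr - 1))
    stop("invalid layout: interfaces must lie inside the image")
  if (any(posterior - anterior <= 0))
    stop("invalid layout: overlapping anterior/posterior interfaces")
  epi <- NULL
  if (isTRUE(lay$epithelium)) {
    epi <- anterior
    if (any(anterior + lay$epiThicknessPx >= posterior))
      stop("invalid layout: epithelial band overlaps posterior interface")
  }

  set.seed(.childSeed(seed, "scene"))
  amp <- matrix(0, nr, nc)
  rows <- seq_len(nr)
  # stroma speckle: Rayleigh amplitude, E[A^2] = 1, with sub-pixel edge cover
  g <- sqrt(stats::rnorm(nr * nc, sd = sqrt(0.5))^2 +
            stats::rnorm(nr * nc, sd = sqrt(0.5))^2)
  speck <- matrix(g, nr, nc)
  for (c in seq_len(nc)) {
    cover <- pmin(1, pmax(0, pmin(rows + 0.5, posterior[c]) -
                               pmax(rows - 0.5, anterior[c])))
    amp[, c] <- speck[, c] * cover
    if (!is.null(epi)) {
      bandCover <- pmin(1, pmax(0, pmin(rows + 0.5, anterior[c] + lay$epiThicknessPx) -
                                   pmax(rows - 0.5, anterior[c])))
      amp[, c] <- amp[, c] * (1 + (lay$epiAmplitude - 1) * bandCover)
    }
  }
  # deterministic bright lines: flat-top sub-pixel kernel of given half-width
  addLine <- function(amp, path, height, halfwidth = 1) {
    for (c in seq_len(nc)) {
      r0 <- floor(path[c] - halfwidth - 1):ceiling(path[c] + halfwidth + 1)
      r0 <- r0[r0 >= 1 & r0 <= nr]
      k <- pmin(1, pmax(0, halfwidth + 1 - abs(r0 - path[c])))
      amp[r0, c] <- amp[r0, c] + height * k
    }
    amp
  }
  wallHw <- (lay$wallThicknessPx - 1) / 2
  for (w in walls) amp <- addLine(amp, w, lay$wallAmplitude, wallHw)
  if (lay$lineAmplitude > 0) {
    amp <- addLine(amp, anterior, lay$lineAmplitude, 0)
    amp <- addLine(amp, posterior, lay$lineAmplitude, 0)
  }

  new("ScenePhantom", amplitude = amp,
      truth = list(anterior = anterior, posterior = posterior,
                   epithelial = epi, walls = walls,
                   hasEpithelium = isTRUE(lay$epithelium)),
      snr = snr, seed = as.integer(seed), layout = lay)
}

#' Build a ground-truth deformation-velocity field
#'
#' Returns a [DeformationField-class] mapping geometric depth z (um), lateral
#' position x (um) and time t (s) to axial velocity (nm/s, positive toward
#' larger depth), plus a uniform bulk-motion term. Available kinds:
#' \describe{
#'   \item{`uniform_strain`}{`v(z) = strain_rate * (z - z_ref_um)` um/s
#'     expressed in nm/s; params `strain_rate` (1/s), `z_ref_um`.}
#'   \item{`exponential_front`}{a de-swelling front decaying away from a
#'     boundary: `v(z) = v_boundary * exp(-(z_b - z)/decay)` for `z <= z_b`
#'     (clamped to `v_boundary` beyond); params `v_boundary_nm_s`,
#'     `decay_um`, `z_boundary_um`.}
#'   \item{`model_trajectory`}{velocities interpolated from a
#'     [ModelTrajectory-class]; params `trajectory`, `z_anterior_um` (depth
#'     of the model's anterior face in the image). Time is absolute model
#'     time in seconds.}
#'   \item{`rigid`}{zero deformation; params `bulk_nm_s`.}
#'   \item{`static`}{zero deformation and zero bulk motion.}
#' }
#' All kinds accept `bulk_nm_s` (constant) or `bulk_fun` (function of t).
#'
#' @param kind field kind tag.
#' @param params named list of parameters for the kind.
#' @return a [DeformationField-class].
#' @examples
#' f <- makeDeformationField("uniform_strain",
#'                           list(strain_rate = -1e-4, z_ref_um = 0))
#' f@velocityFun(500, 0, 0)   # -50 nm/s
#' @export
makeDeformationField <- function(kind, params = list()) {
  bulk <- if (!is.null(params$bulk_fun)) params$bulk_fun
          else {
            b <- if (is.null(params$bulk_nm_s)) 0 else params$bulk_nm_s
            function(t) rep(b, length(t))
          }
  vf <- switch(kind,
    uniform_strain = {
      s <- params$strain_rate
      zr <- if (is.null(params$z_ref_um)) 0 else params$z_ref_um
      if (is.null(s)) stop("uniform_strain requires strain_rate")
      function(z, x, t) 1e3 * s * (z - zr)
    },
    exponential_front = {
      v0 <- params$v_boundary_nm_s; dl <- params$decay_um
      zb <- params$z_boundary_um
      if (is.null(v0) || is.null(dl) || is.null(zb))
        stop("exponential_front requires v_boundary_nm_s, decay_um, z_boundary_um")
      function(z, x, t) v0 * exp(-pmax(0, zb - z) / dl)
    },
    model_trajectory = {
      traj <- params$trajectory; za <- params$z_anterior_um
      if (is.null(traj) || is.null(za))
        stop("model_trajectory requires trajectory and z_anterior_um")
      function(z, x, t) .trajectoryVelocityAt(traj, z - za, t[1])
    },
    rigid = function(z, x, t) rep(0, length(z)),
    static = function(z, x, t) rep(0, length(z)),
    stop(sprintf("unknown deformation field kind '%s'", kind))
  )
  if (kind == "static") bulk <- function(t) rep(0, length(t))
  new("DeformationField", kind = kind, velocityFun = vf, bulkFun = bulk,
      params = params)
}

# velocity (nm/s) at model depth d_um (from anterior face) and absolute model
# time t_s, linearly interpolated in depth and time from a trajectory
.trajectoryVelocityAt <- function(traj, d_um, t_s) {
  tt <- traj@times
  if (t_s < tt[1] - 1e-9 || t_s > tt[length(tt)] + 1e-9)
    stop("time outside trajectory samples")
  j <- findInterval(t_s, tt, all.inside = TRUE)
  w <- (t_s - tt[j]) / (tt[j + 1] - tt[j])
  profAt <- function(k) {
    depth <- traj@boundaryDepth[, k] * 1e4          # cm -> um
    vel <- traj@velocity[, k] * 1e7                 # cm/s -> nm/s
    stats::approx(depth, vel, xout = pmin(pmax(d_um, 0), max(depth)),
                  rule = 2)$y
  }
  v <- (1 - w) * profAt(j) + w * profAt(j + 1)
  v[d_um < 0] <- 0       # above the anterior face: at the reference, static
  v
}

#' Render a scene and field into a complex B-scan stack
#'
#' Produces `geometry@nFrames` complex frames whose per-pixel phase evolves
#' as \eqn{\phi(t) = \phi_0 + (4\pi n_G/\lambda)\int v_{total}\,dt}, where
#' `v_total` is the ground-truth field plus bulk motion, with frozen speckle
#' amplitude from the scene and independent complex Gaussian noise per pixel
#' per frame at the scene SNR. Scatterer displacement is assumed sub-pixel
#' over the stack (amplitude decorrelation neglected), which holds for
#' de-swelling velocities (hundreds of nm/s over a few seconds versus um
#' pixels).
#'
#' @param phantom a [ScenePhantom-class].
#' @param field a [DeformationField-class].
#' @param geometry an [AcquisitionGeometry-class]; `nFrames >= 2`.
#' @param seed integer seed for speckle phase and noise.
#' @param t0 absolute time of the first frame (s), relevant for
#'   time-dependent fields.
#' @param acquiredAt acquisition time since solution transfer (min, for
#'   thickness series bookkeeping).
#' @return a [ComplexFrameStack-class] carrying the scene/field truth.
#' @export
renderFrameStack <- function(phantom, field, geometry, seed = 1L, t0 = 0,
                             acquiredAt = NA_real_) {
  stopifnot(is(phantom, "ScenePhantom"), is(field, "DeformationField"),
            is(geometry, "AcquisitionGeometry"))
  if (geometry@nFrames < 2) stop("need at least 2 frames")
  amp <- phantom@amplitude
  nr <- nrow(amp); nc <- ncol(amp); nf <- geometry@nFrames
  pitchMed <- geometry@axialPitchAir / geometry@groupIndex
  z <- rep((seq_len(nr) - 1) * pitchMed, times = nc)
  x <- rep((seq_len(nc) - 1) * geometry@lateralPitch, each = nr)
  times <- t0 + frameTimes(geometry)

  # velocity per frame, trapezoid-integrated to displacement (nm)
  disp <- array(0, dim = c(nr, nc, nf))
  vPrev <- field@velocityFun(z, x, rep(times[1], 1)) + field@bulkFun(times[1])
  rangeNm <- nr * pitchMed * 1e3
  for (k in 2:nf) {
    vK <- field@velocityFun(z, x, rep(times[k], 1)) + field@bulkFun(times[k])
    dt <- times[k] - times[k - 1]
    inc <- 0.5 * (vPrev + vK) * dt
    if (max(abs(inc)) > rangeNm)
      stop("per-frame displacement exceeds the axial range; scene would wrap out of frame")
    disp[, , k] <- disp[, , k - 1] + inc
    vPrev <- vK
  }

  set.seed(.childSeed(seed, "render"))
  phi0 <- matrix(stats::runif(nr * nc, -pi, pi), nr, nc)
  k4pn <- 4 * pi * geometry@groupIndex / geometry@wavelength   # rad per nm
  frames <- array(complex(real = 0), dim = c(nr, nc, nf))
  sigma <- if (is.finite(phantom@snr)) 1 / phantom@snr else 0
  for (k in seq_len(nf)) {
    ph <- phi0 + k4pn * disp[, , k]
    fr <- amp * exp(1i * ph)
    if (sigma > 0)
      fr <- fr + complex(real = stats::rnorm(nr * nc, sd = sigma / sqrt(2)),
                         imaginary = stats::rnorm(nr * nc, sd = sigma / sqrt(2)))
    frames[, , k] <- fr
  }
  new("ComplexFrameStack", frames = frames, timestamps = times,
      geometry = geometry, acquiredAt = acquiredAt,
      truth = list(scene = phantom, field = field, t0 = t0))
}

#' Ground-truth relative velocity image for a simulated stack
#'
#' Evaluates the stack's true deformation field at the midpoint of the
#' measurement window and re-references it to the given per-column reference
#' rows, i.e. the field a perfect DVI computation would report. Bulk motion
#' cancels by construction.
#'
#' @param stack a simulated [ComplexFrameStack-class] (with truth).
#' @param referenceRows integer vector of per-column reference rows (e.g.
#'   from [computeDVI()]'s output).
#' @return matrix of expected relative velocities (nm/s).
#' @export
groundTruthVelocity <- function(stack, referenceRows) {
  if (is.null(stack@truth$field)) stop("stack carries no ground truth")
  g <- stack@geometry
  field <- stack@truth$field
  nr <- dim(stack@frames)[1]; nc <- dim(stack@frames)[2]
  pitchMed <- g@axialPitchAir / g@groupIndex
  tMid <- mean(range(stack@timestamps))
  z <- rep((seq_len(nr) - 1) * pitchMed, times = nc)
  x <- rep((seq_len(nc) - 1) * g@lateralPitch, each = nr)
  v <- matrix(field@velocityFun(z, x, tMid), nr, nc)
  vRef <- v[cbind(referenceRows, seq_len(nc))]
  sweep(v, 2, vRef, "-")
}

#' Render a de-swelling experiment from a model trajectory
#'
#' For each requested acquisition time, builds a corneal scene whose
#' anterior path is fixed and whose posterior path follows the trajectory's
#' thickness, then renders a frame stack deforming with the trajectory's
#' velocity profile. Together with [segmentCornea()] and [thicknessSeries()]
#' this closes the loop between the osmotic model and the measurement
#' pipeline.
#'
#' @param trajectory a [ModelTrajectory-class].
#' @param geometry an [AcquisitionGeometry-class].
#' @param timesMin acquisition times since transfer (min), within the
#'   trajectory range.
#' @param layout base scene layout overrides (thickness is set per stack).
#' @param snr stromal SNR for the rendered stacks.
#' @param seed root seed; each stack derives its own stream.
#' @return list of [ComplexFrameStack-class] objects with `acquiredAt` set.
#' @export
renderTrajectoryStacks <- function(trajectory, geometry, timesMin,
                                   layout = list(), snr = Inf, seed = 1L) {
  lay <- utils::modifyList(.defaultLayout(), layout)
  pitchMed <- geometry@axialPitchAir / geometry@groupIndex
  thickUm <- stats::approx(trajectory@times, trajectory@thickness * 1e4,
                           xout = timesMin * 60)$y
  if (any(is.na(thickUm))) stop("timesMin outside the trajectory range")
  lapply(seq_along(timesMin), function(i) {
    layI <- lay
    layI$thicknessPx <- thickUm[i] / pitchMed
    scene <- makeCornealScene(geometry, layI, snr = snr,
                              seed = .childSeed(seed, paste0("scene", i)))
    field <- makeDeformationField("model_trajectory",
      list(trajectory = trajectory,
           z_anterior_um = (layI$anteriorRow - 1) * pitchMed))
    renderFrameStack(scene, field, geometry,
                     seed = .childSeed(seed, paste0("stack", i)),
                     t0 = timesMin[i] * 60, acquiredAt = timesMin[i])
  })
}
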