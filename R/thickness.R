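# Automated corneal thickness measurement from segmented stacks.

#' Per-column geometric corneal thickness
#'
#' `(posterior_row - anterior_row) * axialPitchAir / n_G`: the optical
#' pixel separation converted to geometric thickness with a constant group
#' refractive index.
#'
#' @param interfaces a [CornealInterfaces-class].
#' @param geometry an [AcquisitionGeometry-class].
#' @return numeric vector of per-column thickness (um).
#' @examples
#' # rows 100/300, 5 um/px air, n_G = 1.37 -> ~729.9 um
#' @export
thicknessPerColumn <- function(interfaces, geometry) {
  sep <- interfaces@posterior@rows - interfaces@anterior@rows
  if (any(sep <= 0)) stop("anterior/posterior ordering violation")
  sep * geometry@axialPitchAir / geometry@groupIndex
}

#' Corneal thickness time series over a set of stacks
#'
#' Segments each stack's first frame, averages the per-column thickness over
#' a central fraction of columns (edge columns are prone to mounting
#' artefacts), and orders the result by acquisition time. Stacks whose
#' segmentation fails are recorded as `NA` gaps rather than aborting the
#' series, so an interrupted acquisition still yields a usable curve.
#' Irregular sampling intervals (e.g. every minute early, every ten minutes
#' late) are supported as-is.
#'
#' @param stacks list of [ComplexFrameStack-class] objects with `acquiredAt`
#'   set (minutes since solution transfer).
#' @param config a [segmentationConfig()] shared by all time points.
#' @param centralFraction fraction of central columns averaged (default
#'   0.8).
#' @return a [ThicknessSeries-class].
#' @export
thicknessSeries <- function(stacks, config = segmentationConfig(),
                            centralFraction = 0.8) {
  if (length(stacks) < 1) stop("need at least one stack")
  times <- vapply(stacks, function(s) s@acquiredAt, numeric(1))
  if (any(is.na(times))) stop("every stack needs an acquiredAt time")
  ord <- order(times)
  stacks <- stacks[ord]; times <- times[ord]
  geom <- stacks[[1]]@geometry
  n <- length(stacks)
  meanT <- rep(NA_real_, n); sdT <- rep(NA_real_, n); nCol <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      seg <- segmentCornea(amplitudeImage(stacks[[i]]), config,
                           imageId = sprintf("t%.6g", times[i]))
      th <- thicknessPerColumn(seg, stacks[[i]]@geometry)
      nc <- length(th)
      keep <- max(1L, round(nc * centralFraction))
      lo <- floor((nc - keep) / 2) + 1L
      th[lo:(lo + keep - 1L)]
    }, error = function(e) NULL)
    if (!is.null(res)) {
      meanT[i] <- mean(res); sdT[i] <- stats::sd(res); nCol[i] <- length(res)
    }
  }
  if (all(is.na(meanT))) stop("all time points failed to segment")
  new("ThicknessSeries", timeMin = times, meanThicknessUm = meanT,
      sdUm = sdT, nColumns = nCol, groupIndex = geom@groupIndex)
}
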