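# Iterative graph-search segmentation: energy maps, dynamic-programming
# minimum-energy left-to-right paths, iterated path extraction with blocking,
# column-wise flattening, and the full corneal segmentation pipeline.

#' Build a per-pixel energy map
#'
#' The image is median-filtered, converted to an energy (either
#' `max(smoothed) - smoothed`, so bright structures attract paths, or
#' `max(|d/drow smoothed|) - |d/drow smoothed|`, so strong vertical edges
#' attract paths), then boxcar-smoothed. The result is finite, non-negative
#' and the same shape as the input.
#'
#' @param image non-negative amplitude matrix.
#' @param kind `"inverted_amplitude"` or `"inverted_vertical_gradient"`.
#' @param medianSize odd median filter size (pixels), default 3.
#' @param boxcarSize odd boxcar size (pixels), default 5.
#' @return an [EnergyMap-class].
#' @export
buildEnergy <- function(image, kind = c("inverted_amplitude",
                                        "inverted_vertical_gradient"),
                        medianSize = 3L, boxcarSize = 5L) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("non-finite input pixels")
  if (!.isOdd(medianSize) || !.isOdd(boxcarSize) ||
      medianSize < 1 || boxcarSize < 1)
    stop("filter sizes must be odd and >= 1")
  sm <- medianFilter2(image, medianSize)
  e <- if (kind == "inverted_amplitude") {
    max(sm) - sm
  } else {
    g <- abs(verticalGradient(sm))
    max(g) - g
  }
  e <- boxcarFilter2(e, boxcarSize)
  e <- pmax(e, 0)   # guard tiny negative rounding
  new("EnergyMap", energy = e, kind = kind,
      medianSize = as.integer(medianSize), boxcarSize = as.integer(boxcarSize))
}

.energyOf <- function(energy) {
  if (is(energy, "EnergyMap")) energy@energy else energy
}

#' Minimum-energy left-to-right path
#'
#' Dynamic programming over columns: among all paths visiting one row per
#' column, with per-column vertical steps of at most `stepBound` pixels and
#' avoiding blocked pixels, returns the path of minimum total energy. Ties
#' are broken toward the lexicographically smallest row sequence from the
#' leftmost column, which makes the result deterministic.
#'
#' @param energy an [EnergyMap-class] or a plain non-negative matrix.
#' @param blocked optional logical matrix of forbidden pixels.
#' @param stepBound maximum |row change| between adjacent columns (default 1).
#' @param label label to attach to the returned path.
#' @return an [InterfacePath-class].
#' @export
minEnergyPath <- function(energy, blocked = NULL, stepBound = 1L,
                          label = "path") {
  E <- .energyOf(energy)
  nr <- nrow(E); nc <- ncol(E)
  stepBound <- as.integer(stepBound)
  cost <- E
  if (!is.null(blocked)) {
    stopifnot(identical(dim(blocked), dim(E)))
    cost[blocked] <- Inf
  }
  # cost-to-go from (r, c) to the last column
  togo <- matrix(0, nr, nc)
  togo[, nc] <- cost[, nc]
  if (nc > 1) {
    for (c in (nc - 1):1) {
      w <- togo[, c + 1]
      m <- w
      if (stepBound >= 1) for (s in seq_len(stepBound)) {
        m <- pmin(m, c(w[-seq_len(s)], rep(Inf, s)),
                  c(rep(Inf, s), w[seq_len(nr - s)]))
      }
      togo[, c] <- cost[, c] + m
    }
  }
  if (!is.finite(min(togo[, 1])))
    stop(structure(class = c("dvioct_no_path", "error", "condition"),
                   list(message = "no unblocked path exists under the step bound",
                        call = sys.call(-1))))
  path <- integer(nc)
  path[1] <- which.min(togo[, 1])          # first index = smallest row on tie
  if (nc > 1) for (c in 2:nc) {
    lo <- max(1L, path[c - 1] - stepBound)
    hi <- min(nr, path[c - 1] + stepBound)
    seg <- togo[lo:hi, c]
    path[c] <- lo + which.min(seg) - 1L
  }
  new("InterfacePath", rows = path, label = label, stepBound = stepBound)
}

#' Iterated minimum-energy paths with blocking
#'
#' Extracts `nPaths` paths in discovery order; before searching for path
#' k + 1, all pixels within `blockHalfwidth` rows of paths 1..k are blocked.
#'
#' @param energy an [EnergyMap-class] or matrix.
#' @param nPaths number of paths to extract.
#' @param blockHalfwidth vertical blocking half-width (pixels).
#' @param blocked optional initial blocked mask (e.g. user block masks).
#' @param stepBound per-column step bound.
#' @return list of [InterfacePath-class] in discovery order.
#' @export
iteratePaths <- function(energy, nPaths = 1L, blockHalfwidth = 10L,
                         blocked = NULL, stepBound = 1L) {
  E <- .energyOf(energy)
  if (nPaths < 1) stop("nPaths must be >= 1")
  blk <- if (is.null(blocked)) matrix(FALSE, nrow(E), ncol(E)) else blocked
  out <- vector("list", nPaths)
  for (k in seq_len(nPaths)) {
    p <- tryCatch(minEnergyPath(E, blk, stepBound),
                  dvioct_no_path = function(e) {
                    stop(structure(class = c("dvioct_no_path", "error", "condition"),
                         list(message = sprintf(
                           "blocking exhausted the image after %d of %d paths",
                           k - 1L, nPaths), call = NULL, found = k - 1L)))
                  })
    out[[k]] <- p
    blk <- blk | .blockAroundPath(dim(E), p@rows, blockHalfwidth)
  }
  out
}

.blockAroundPath <- function(dims, rows, halfwidth) {
  nr <- dims[1]; nc <- dims[2]
  m <- matrix(FALSE, nr, nc)
  for (c in seq_len(nc)) {
    lo <- max(1L, rows[c] - halfwidth); hi <- min(nr, rows[c] + halfwidth)
    m[lo:hi, c] <- TRUE
  }
  m
}

#' Flatten an image to an interface profile
#'
#' Shifts each column vertically so the given path maps onto a constant
#' target row ("making the cornea flat"); out-of-range pixels are zero
#' padded and marked invalid. The per-column shifts are recorded so paths
#' found in the flattened frame can be mapped back exactly.
#'
#' @param image numeric matrix.
#' @param path an [InterfacePath-class] (or integer row vector).
#' @param targetRow row the path is mapped to; default the rounded median
#'   path row.
#' @return list with `image`, `valid` (logical), `shifts` (per column),
#'   `targetRow`.
#' @seealso [unflattenRows()]
#' @export
flattenToProfile <- function(image, path, targetRow = NULL) {
  rows <- if (is(path, "InterfacePath")) path@rows else as.integer(path)
  stopifnot(length(rows) == ncol(image))
  if (is.null(targetRow)) targetRow <- as.integer(round(stats::median(rows)))
  nr <- nrow(image); nc <- ncol(image)
  shifts <- as.integer(targetRow - rows)
  out <- matrix(0, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (c in seq_len(nc)) {
    src <- seq_len(nr) - shifts[c]
    ok <- src >= 1 & src <= nr
    out[ok, c] <- image[src[ok], c]
    valid[ok, c] <- TRUE
  }
  list(image = out, valid = valid, shifts = shifts,
       targetRow = as.integer(targetRow))
}

#' Map rows found in a flattened image back to original coordinates
#'
#' @param rows integer row vector (one per column) in flattened coordinates.
#' @param shifts the `shifts` recorded by [flattenToProfile()].
#' @return integer rows in the original image.
#' @export
unflattenRows <- function(rows, shifts) as.integer(rows - shifts)

#' Segmentation configuration
#'
#' Defaults follow the lowest robust values for the synthetic vial scenes:
#' 3x3 median, 3x3 boxcar, blocking half-width 10 pixels, per-column step
#' bound 1 pixel. `flattenMargins` gives the rows kept above/below the
#' flattened approximate anterior profile before the final gradient search;
#' `blockMask` is an optional user-supplied logical matrix of pixels to
#' exclude (the reproducible replacement for manual review of false paths).
#'
#' @param variant `"with_epithelium"` or `"without_epithelium"`.
#' @param rowRange optional `c(first, last)` row range to consider.
#' @param nWalls number of container-wall lines to find and remove.
#' @param medianSize,boxcarSize energy filter sizes (odd).
#' @param blockHalfwidth vertical blocking half-width (pixels).
#' @param stepBound per-column step bound (pixels).
#' @param flattenMargins `c(above, below)` rows kept around the flattened
#'   anterior profile.
#' @param blockMask optional logical matrix of blocked pixels.
#' @return a named list of class `segmentationConfig`.
#' @export
segmentationConfig <- function(variant = c("with_epithelium",
                                           "without_epithelium"),
                               rowRange = NULL, nWalls = 2L,
                               medianSize = 3L, boxcarSize = 3L,
                               blockHalfwidth = 10L, stepBound = 1L,
                               flattenMargins = c(25L, 300L),
                               blockMask = NULL) {
  structure(list(variant = match.arg(variant), rowRange = rowRange,
                 nWalls = as.integer(nWalls),
                 medianSize = as.integer(medianSize),
                 boxcarSize = as.integer(boxcarSize),
                 blockHalfwidth = as.integer(blockHalfwidth),
                 stepBound = as.integer(stepBound),
                 flattenMargins = as.integer(flattenMargins),
                 blockMask = blockMask),
            class = "segmentationConfig")
}

#' Segment the corneal interfaces of a structural B-scan
#'
#' Full iterative graph-search pipeline: (1) restrict to the configured
#' vertical range; (2) find the bright container-wall lines with the
#' inverted-amplitude energy and block them; (3) find an approximate
#' anterior profile — via the amplitude energy when a scattering epithelial
#' band is present, via the vertical-gradient energy otherwise; (4) flatten
#' the image to that profile and discard rows outside the configured
#' margins; (5) run a final vertical-gradient search for the two corneal
#' interfaces in the flattened frame; (6) map the paths back to original
#' coordinates. The upper path becomes the anterior, the lower the
#' posterior interface.
#'
#' @param image non-negative amplitude matrix (typically frame 1 of a
#'   stack).
#' @param config a [segmentationConfig()].
#' @param imageId identifier recorded in the result.
#' @return a [CornealInterfaces-class]; auxiliary paths hold the walls and,
#'   for `with_epithelium` scenes, the epithelial profile.
#' @examples
#' sc <- makeCornealScene(seed = 7)
#' seg <- segmentCornea(amplitudeImage(sc), segmentationConfig())
#' mean(abs(anteriorPath(seg) - sc@truth$anterior))
#' @export
segmentCornea <- function(image, config = segmentationConfig(),
                          imageId = "image") {
  stopifnot(inherits(config, "segmentationConfig"))
  nrFull <- nrow(image)
  r0 <- 0L
  sub <- image
  blockedInit <- config$blockMask
  if (!is.null(config$rowRange)) {
    rr <- config$rowRange
    sub <- image[rr[1]:rr[2], , drop = FALSE]
    r0 <- rr[1] - 1L
    if (!is.null(blockedInit))
      blockedInit <- blockedInit[rr[1]:rr[2], , drop = FALSE]
  }
  nr <- nrow(sub); nc <- ncol(sub)
  blk <- if (is.null(blockedInit)) matrix(FALSE, nr, nc) else blockedInit

  ampE <- buildEnergy(sub, "inverted_amplitude", config$medianSize,
                      config$boxcarSize)
  walls <- iteratePaths(ampE, config$nWalls, config$blockHalfwidth,
                        blocked = blk, stepBound = config$stepBound)
  for (w in walls)
    blk <- blk | .blockAroundPath(dim(sub), w@rows, config$blockHalfwidth)

  # approximate anterior profile for flattening
  if (config$variant == "with_epithelium") {
    approxAnt <- minEnergyPath(ampE, blk, config$stepBound, "epithelial")
  } else {
    gradE <- buildEnergy(sub, "inverted_vertical_gradient", config$medianSize,
                         config$boxcarSize)
    two <- iteratePaths(gradE, 2L, config$blockHalfwidth, blocked = blk,
                        stepBound = config$stepBound)
    means <- vapply(two, function(p) mean(p@rows), numeric(1))
    approxAnt <- two[[which.min(means)]]
  }

  flat <- flattenToProfile(sub, approxAnt)
  lo <- max(1L, flat$targetRow - config$flattenMargins[1])
  hi <- min(nr, flat$targetRow + config$flattenMargins[2])
  fsub <- flat$image[lo:hi, , drop = FALSE]
  fblk <- !flat$valid[lo:hi, , drop = FALSE]
  # keep wall blocks and user blocks in flattened coordinates
  blkFlat <- matrix(FALSE, nr, nc)
  for (c in seq_len(nc)) {
    src <- seq_len(nr) - flat$shifts[c]
    ok <- src >= 1 & src <= nr
    blkFlat[ok, c] <- blk[src[ok], c]
  }
  fblk <- fblk | blkFlat[lo:hi, , drop = FALSE]
  # shield pixels adjacent to the pad boundary from its artificial edge
  fblk <- fblk | .shiftMat(fblk, 1L) | .shiftMat(fblk, -1L) |
          .shiftMat(fblk, 2L) | .shiftMat(fblk, -2L)

  gradE2 <- buildEnergy(fsub, "inverted_vertical_gradient", config$medianSize,
                        config$boxcarSize)
  two <- iteratePaths(gradE2, 2L, config$blockHalfwidth, blocked = fblk,
                      stepBound = config$stepBound)
  means <- vapply(two, function(p) mean(p@rows), numeric(1))
  antFlat <- two[[which.min(means)]]@rows + (lo - 1L)
  postFlat <- two[[which.max(means)]]@rows + (lo - 1L)
  antRows <- unflattenRows(antFlat, flat$shifts) + r0
  postRows <- unflattenRows(postFlat, flat$shifts) + r0

  segFail <- function(why)
    stop(structure(class = c("dvioct_segmentation_failure", "error",
                             "condition"),
                   list(message = paste("segmentation failure:", why,
                        "- consider config block masks"), call = NULL)))
  if (!all(antRows < postRows))
    segFail("anterior/posterior ordering violated")
  # the claimed cornea must be a scattering band: require clear contrast
  # between the enclosed region and the background (wall reflections and a
  # margin around the candidate interfaces excluded)
  inMask <- matrix(FALSE, nrFull, ncol(image))
  outMask <- matrix(TRUE, nrFull, ncol(image))
  for (c in seq_len(ncol(image))) {
    inMask[antRows[c]:postRows[c], c] <- TRUE
    lo <- max(1L, antRows[c] - 5L); hi <- min(nrFull, postRows[c] + 5L)
    outMask[lo:hi, c] <- FALSE
  }
  for (w in walls) {
    wr <- w@rows + r0
    for (c in seq_len(ncol(image))) {
      lo <- max(1L, wr[c] - 5L); hi <- min(nrFull, wr[c] + 5L)
      outMask[lo:hi, c] <- FALSE
    }
  }
  if (!any(outMask)) outMask <- !inMask
  if (mean(image[inMask]) <= 2 * mean(image[outMask]))
    segFail("no scattering band between the candidate interfaces")
  aux <- lapply(seq_along(walls), function(i)
    new("InterfacePath", rows = walls[[i]]@rows + r0, label = "vial_wall",
        stepBound = config$stepBound))
  names(aux) <- paste0("wall", seq_along(walls))
  if (config$variant == "with_epithelium")
    aux$epithelial <- new("InterfacePath", rows = approxAnt@rows + r0,
                          label = "epithelial", stepBound = config$stepBound)
  # unflattening can add the approximate-anterior step to the flat-frame
  # step, so the mapped paths satisfy twice the search bound
  new("CornealInterfaces",
      anterior = new("InterfacePath", rows = antRows, label = "anterior",
                     stepBound = 2L * config$stepBound),
      posterior = new("InterfacePath", rows = postRows, label = "posterior",
                      stepBound = 2L * config$stepBound),
      auxiliary = aux, variant = config$variant, imageId = imageId)
}
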