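# I/O: a self-describing binary container for complex frame stacks (no
# community standard exists for complex OCT B-scan stacks), TIFF previews,
# CSV tables and YAML run configurations.

.STACK_MAGIC <- "DVISTK01"

#' Write a complex frame stack to a single-file container
#'
#' Layout: an 8-byte magic string, a 4-byte header length, a JSON header
#' (dimensions, timestamps, acquisition geometry, acquisition time), then
#' the full-precision float64 real and imaginary parts in column-major
#' order. The round trip is lossless (bit-identical arrays and metadata).
#' Simulation ground truth is not serialised.
#'
#' @param stack a [ComplexFrameStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ComplexFrameStack"))
  g <- stack@geometry
  header <- jsonlite::toJSON(list(
    dims = dim(stack@frames), timestamps = stack@timestamps,
    acquiredAt = stack@acquiredAt,
    geometry = list(wavelength = g@wavelength, groupIndex = g@groupIndex,
                    frameRate = g@frameRate, axialPitchAir = g@axialPitchAir,
                    lateralPitch = g@lateralPitch, nFrames = g@nFrames)),
    digits = NA, auto_unbox = FALSE)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.STACK_MAGIC), con)
  writeBin(length(hraw), con, size = 4L)
  writeBin(hraw, con)
  writeBin(as.vector(Re(stack@frames)), con, size = 8L)
  writeBin(as.vector(Im(stack@frames)), con, size = 8L)
  invisible(path)
}

#' Read a complex frame stack container
#'
#' @param path file written by [writeStack()].
#' @return a [ComplexFrameStack-class].
#' @export
readStack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmtErr <- function(what)
    stop(sprintf("malformed stack container '%s': %s", path, what))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, .STACK_MAGIC)) fmtErr("bad magic")
  hlen <- readBin(con, "integer", 1L, size = 4L)
  if (length(hlen) != 1 || is.na(hlen) || hlen <= 0) fmtErr("bad header length")
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) fmtErr("truncated header")
  h <- tryCatch(jsonlite::fromJSON(rawToChar(hraw)),
                error = function(e) fmtErr("unparseable header"))
  d <- as.integer(h$dims)
  n <- prod(d)
  re <- readBin(con, "double", n, size = 8L)
  if (length(re) < n) fmtErr("truncated dataset /real")
  im <- readBin(con, "double", n, size = 8L)
  if (length(im) < n) fmtErr("truncated dataset /imag")
  g <- h$geometry
  geom <- AcquisitionGeometry(wavelength = g$wavelength,
                              groupIndex = g$groupIndex,
                              frameRate = g$frameRate,
                              axialPitchAir = g$axialPitchAir,
                              lateralPitch = g$lateralPitch,
                              nFrames = g$nFrames)
  new("ComplexFrameStack",
      frames = array(complex(real = re, imaginary = im), dim = d),
      timestamps = as.numeric(h$timestamps),
      geometry = geom, acquiredAt = as.numeric(h$acquiredAt)[1],
      truth = list())
}

#' Write an amplitude image (or stack preview) as TIFF
#'
#' Images are min-max normalised to \[0, 1\] and written as 32-bit float
#' TIFF; a stack becomes a multi-page TIFF of per-frame amplitudes.
#' Previews are for inspection, not a lossless store (use [writeStack()]).
#'
#' @param x numeric matrix, or a [ComplexFrameStack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImage <- function(x, path) {
  norm <- function(m) {
    lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
    m[is.na(m)] <- lo
    if (hi > lo) (m - lo) / (hi - lo) else m * 0
  }
  if (is(x, "ComplexFrameStack")) {
    pages <- lapply(seq_len(dim(x@frames)[3]),
                    function(k) norm(Mod(x@frames[, , k])))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(norm(x), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a (first-page) TIFF image as a matrix
#'
#' @param path TIFF file.
#' @return numeric matrix.
#' @export
readImage <- function(path) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Write/read a data frame as CSV
#'
#' Thin wrappers with fixed conventions (no row names) so pipeline outputs
#' are byte-stable across runs.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
writeTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) utils::read.csv(path)

## run configuration ----------------------------------------------------------

.configSchema <- function() {
  list(seed = NULL, outDir = NULL, stages = NULL,
       geometry = c("wavelength", "groupIndex", "frameRate", "axialPitchAir",
                    "lateralPitch", "nFrames"),
       scene = c("snr", "layout"),
       model = c("C", "gamma", "kOverMu", "Lendo", "H0", "Heq",
                 "anteriorBoundary", "Lepi", "nElements", "dryThickness",
                 "sampleTimesMin"),
       segmentation = c("variant", "nWalls", "medianSize", "boxcarSize",
                        "blockHalfwidth", "stepBound", "flattenMargins"),
       dvi = c("refractiveIndex", "boxcarSize", "referenceHalfwidth",
               "profileFrom"),
       fit = c("enabled", "gridN", "timesMin", "bounds", "thicknessWeight"))
}

#' Validate a pipeline run configuration
#'
#' Checks every key (top-level and per-section) against the configuration
#' schema; an unknown key raises an error naming it.
#'
#' @param config named list (e.g. from [readRunConfig()]).
#' @return the config, invisibly, if valid.
#' @export
validateRunConfig <- function(config) {
  schema <- .configSchema()
  for (key in names(config)) {
    if (!(key %in% names(schema)))
      stop(sprintf("unknown config key '%s'", key))
    sub <- schema[[key]]
    if (!is.null(sub) && is.list(config[[key]])) {
      for (k2 in names(config[[key]])) {
        if (!(k2 %in% sub))
          stop(sprintf("unknown config key '%s.%s'", key, k2))
      }
    }
  }
  if (!is.null(config$scene$layout)) {
    bad <- setdiff(names(config$scene$layout), names(.defaultLayout()))
    if (length(bad))
      stop(sprintf("unknown config key 'scene.layout.%s'", bad[1]))
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file.
#' @return validated named list.
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}
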