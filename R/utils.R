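# Shared numerical helpers: phase wrapping, separable filters, gradients.

#' Wrap phase angles into (-pi, pi]
#'
#' @param x numeric vector/array of phases (rad).
#' @return phases wrapped to the principal interval.
#' @keywords internal
wrapPhase <- function(x) {
  y <- x - 2 * pi * round(x / (2 * pi))
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

#' Boxcar (moving-average) filter with shrink-window edges
#'
#' Averages over a `size` x `size` window; at the image border the window is
#' clipped to the image so the normalisation shrinks with it. `NA` pixels are
#' excluded from both numerator and denominator, so a masked image stays
#' masked (pixels with no valid neighbour stay `NA`).
#'
#' @param x numeric matrix (may contain `NA`).
#' @param size odd window size in pixels; `1` returns `x` unchanged.
#' @return filtered matrix, same shape; `NA` where no valid pixel in window.
#' @keywords internal
boxcarFilter2 <- function(x, size) {
  stopifnot(is.matrix(x), size >= 1, size %% 2 == 1)
  if (size == 1) return(x)
  h <- (size - 1L) / 2L
  valid <- !is.na(x)
  xs <- x
  xs[!valid] <- 0
  sums <- .windowSum(xs, h)
  cnts <- .windowSum(valid + 0, h)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

# summed-area table window sum over (2h+1)^2 clipped windows
.windowSum <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(1L, seq_len(nr) - h); r2 <- pmin(nr, seq_len(nr) + h)
  c1 <- pmax(1L, seq_len(nc) - h); c2 <- pmin(nc, seq_len(nc) + h)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# shift a matrix down (dr > 0) / right (dc > 0) with edge replication
.shiftMat <- function(x, dr, dc = 0L) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  x[ri, ci, drop = FALSE]
}

#' 2-D median filter
#'
#' `size = 3` uses a vectorised 9-element sorting network (exchange network of
#' pmin/pmax), other odd sizes fall back to an explicit per-pixel median.
#' Edges are handled by replicate padding.
#'
#' @param x numeric matrix.
#' @param size odd window size; `1` is the identity.
#' @return median-filtered matrix.
#' @keywords internal
medianFilter2 <- function(x, size) {
  stopifnot(is.matrix(x), size >= 1, size %% 2 == 1)
  if (size == 1) return(x)
  if (any(!is.finite(x))) stop("medianFilter2: non-finite input pixels")
  h <- (size - 1L) / 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  planes <- lapply(seq_len(nrow(offs)),
                   function(i) .shiftMat(x, offs$dr[i], offs$dc[i]))
  if (size == 3L) return(.median9(planes))
  arr <- array(unlist(planes, use.names = FALSE), dim = c(dim(x), length(planes)))
  apply(arr, c(1L, 2L), stats::median)
}

# Paeth 19-exchange median-of-9 network, vectorised over matrices
.median9 <- function(p) {
  xch <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  p[[5]]
}

#' Vertical (axial) finite-difference gradient
#'
#' Central differences in the row (depth) direction, one-sided at the first
#' and last row.
#'
#' @param x numeric matrix.
#' @return matrix of d(x)/d(row).
#' @keywords internal
verticalGradient <- function(x) {
  nr <- nrow(x)
  if (nr < 2) stop("verticalGradient: need at least 2 rows")
  g <- x
  g[2:(nr - 1), ] <- (x[3:nr, , drop = FALSE] - x[1:(nr - 2), , drop = FALSE]) / 2
  g[1, ] <- x[2, ] - x[1, ]
  g[nr, ] <- x[nr, ] - x[nr - 1, ]
  g
}

# deterministic child seed derived from a root seed and a stream label
.childSeed <- function(seed, stream) {
  ch <- utf8ToInt(as.character(stream))
  s <- sum(ch * 31^(seq_along(ch) %% 7)) %% 1000003
  as.integer((as.numeric(seed) * 2654435 + s) %% 2147483647)
}

.isOdd <- function(k) k %% 2 == 1
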