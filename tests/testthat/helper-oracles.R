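# Independent oracles and small builders shared by the tests.

# Exhaustive minimum-energy path enumeration (with step bound and optional
# blocking); returns the minimal total and the lexicographically smallest
# optimal row sequence. Independent of the DP implementation.
bruteForcePath <- function(E, stepBound = 1L, blocked = NULL) {
  nr <- nrow(E); nc <- ncol(E)
  if (is.null(blocked)) blocked <- matrix(FALSE, nr, nc)
  best <- list(total = Inf, rows = NULL)
  recurse <- function(col, rows, total) {
    if (col > nc) {
      if (total < best$total ||
          (total == best$total && !is.null(best$rows) &&
           .lexLess(rows, best$rows))) {
        best <<- list(total = total, rows = rows)
      }
      return(invisible())
    }
    cand <- if (col == 1) seq_len(nr)
            else max(1L, rows[col - 1] - stepBound):
                 min(nr, rows[col - 1] + stepBound)
    for (r in cand) {
      if (!blocked[r, col]) recurse(col + 1L, c(rows, r), total + E[r, col])
    }
  }
  recurse(1L, integer(0), 0)
  best
}

.lexLess <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# brute-force temporal unwrapping: per step, try all 2*pi shifts in a wide
# window and keep the one minimising the absolute increment
bruteForceUnwrap <- function(series) {
  out <- series[1]
  for (k in 2:length(series)) {
    cand <- series[k] + 2 * pi * (-5:5)
    out <- c(out, cand[which.min(abs(cand - out[k - 1]))])
  }
  out
}

# small fast scene for tests that do not need the full default frame
smallLayout <- function(...) {
  utils::modifyList(
    list(nrow = 200L, ncol = 60L, wallRows = c(15, 185), anteriorRow = 50,
         thicknessPx = 90, curvaturePx = 4),
    list(...))
}

smallGeometry <- function(...) AcquisitionGeometry(...)
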