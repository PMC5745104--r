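# Graph-search segmentation: energy construction, DP path search against
# exhaustive enumeration, iterated blocking, flattening, full pipeline.

test_that("median filter matches a per-pixel median oracle", {
  set.seed(1)
  x <- matrix(runif(30 * 12), 30, 12)
  got <- dvioct:::medianFilter2(x, 3L)
  pad <- function(m, dr, dc) dvioct:::.shiftMat(m, dr, dc)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  arr <- array(unlist(lapply(seq_len(9), function(i)
    pad(x, offs$dr[i], offs$dc[i]))), dim = c(30, 12, 9))
  expect_equal(got, apply(arr, c(1, 2), median))
})

test_that("energy construction follows its definitions", {
  const <- matrix(5, 20, 10)
  e <- buildEnergy(const, "inverted_amplitude")
  expect_true(all(e@energy == 0))

  img <- matrix(0, 20, 10); img[7, ] <- 10
  e2 <- buildEnergy(img, "inverted_amplitude", medianSize = 1L,
                    boxcarSize = 1L)
  expect_true(all(apply(e2@energy, 2, which.min) == 7))

  step <- rbind(matrix(0, 10, 8), matrix(1, 10, 8))
  e3 <- buildEnergy(step, "inverted_vertical_gradient", medianSize = 1L,
                    boxcarSize = 1L)
  expect_true(all(apply(e3@energy, 2, which.min) %in% 10:11))

  expect_error(buildEnergy(matrix(c(1, NA, 1, 1), 2, 2), "inverted_amplitude"),
               "non-finite")
  expect_error(buildEnergy(const, "inverted_amplitude", medianSize = 2L),
               "odd")
})

test_that("DP path equals exhaustive enumeration on small grids", {
  E <- matrix(c(1, 9, 1, 9, 1, 9, 1, 9, 1), 3, 3)
  bf <- bruteForcePath(E, 1L)
  p <- minEnergyPath(E, stepBound = 1L)
  expect_equal(sum(E[cbind(pathRows(p), 1:3)]), bf$total)
  expect_equal(pathRows(p), bf$rows)

  set.seed(99)
  for (i in 1:40) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    sb <- sample(1:2, 1)
    E <- matrix(sample(0:9, nr * nc, replace = TRUE), nr, nc)
    bf <- bruteForcePath(E, sb)
    p <- minEnergyPath(E, stepBound = sb)
    expect_equal(pathRows(p), bf$rows,
                 info = sprintf("grid %dx%d step %d rep %d", nr, nc, sb, i))
  }
})

test_that("DP respects block masks and reports no-path", {
  E <- matrix(1, 4, 4)
  blocked <- matrix(FALSE, 4, 4); blocked[, 2] <- TRUE
  expect_error(minEnergyPath(E, blocked), class = "dvioct_no_path")
  blocked2 <- matrix(FALSE, 4, 4); blocked2[1:2, 3] <- TRUE
  bf <- bruteForcePath(E + row(E) / 10, 1L, blocked2)
  p <- minEnergyPath(E + row(E) / 10, blocked2, 1L)
  expect_equal(pathRows(p), bf$rows)
})

test_that("ties break toward the smallest rows and shifts do not matter", {
  E <- matrix(1, 5, 6)
  expect_equal(pathRows(minEnergyPath(E)), rep(1L, 6))
  E2 <- matrix(runif(30), 5, 6)
  p1 <- pathRows(minEnergyPath(E2))
  p2 <- pathRows(minEnergyPath(E2 + 17.3))
  expect_equal(p1, p2)
  E3 <- matrix(2, 5, 6); E3[4, ] <- 0
  expect_equal(pathRows(minEnergyPath(E3)), rep(4L, 6))
})

test_that("iterated search with blocking finds separated structures", {
  E <- matrix(5, 40, 8); E[10, ] <- 0; E[30, ] <- 0
  ps <- iteratePaths(E, 2L, blockHalfwidth = 5L)
  expect_setequal(vapply(ps, function(p) p@rows[1], integer(1)), c(10L, 30L))
  expect_equal(pathRows(iteratePaths(E, 1L)[[1]]),
               pathRows(minEnergyPath(E)))
  expect_error(iteratePaths(E, 5L, blockHalfwidth = 15L),
               class = "dvioct_no_path")
})

test_that("amplitude search recovers walls and epithelial band on a phantom", {
  sc <- makeCornealScene(layout = smallLayout(epiThicknessPx = 4), snr = 50,
                         seed = 13)
  e <- buildEnergy(sc@amplitude, "inverted_amplitude", 3L, 3L)
  ps <- iteratePaths(e, 3L, blockHalfwidth = 10L)
  found <- vapply(ps, function(p) mean(pathRows(p)), numeric(1))
  wallTruth <- vapply(sc@truth$walls, mean, numeric(1))
  # two of the three paths are the walls, within a pixel
  wallErr <- vapply(wallTruth, function(w) min(abs(found - w)), numeric(1))
  expect_true(all(wallErr <= 1))
  # the third lies inside the epithelial band
  isWall <- vapply(found, function(f) min(abs(f - wallTruth)) <= 3, logical(1))
  expect_equal(sum(isWall), 2L)
  off <- pathRows(ps[[which(!isWall)]]) - sc@truth$anterior
  expect_true(all(off > -1 & off < 5))
})

test_that("flattening is invertible and straightens a curved path", {
  img <- matrix(runif(200), 20, 10)
  flatPath <- rep(8L, 10)
  fl <- flattenToProfile(img, flatPath, targetRow = 8L)
  expect_equal(fl$image, img)
  tilt <- as.integer(round(seq(5, 14, length.out = 10)))
  fl2 <- flattenToProfile(img, tilt)
  for (c in 1:10) {
    src <- which(fl2$valid[, c])
    expect_equal(fl2$image[src, c], img[src - fl2$shifts[c], c])
  }
  expect_equal(unflattenRows(rep(fl2$targetRow, 10), fl2$shifts), tilt)

  sc <- makeCornealScene(layout = smallLayout(curvaturePx = 6), seed = 14)
  seg <- segmentCornea(amplitudeImage(sc), segmentationConfig())
  fl3 <- flattenToProfile(amplitudeImage(sc), seg@anterior)
  expect_lte(diff(range(unflattenRows(
    rep(fl3$targetRow, length(fl3$shifts)), fl3$shifts) -
    anteriorPath(seg))), 0)
})

test_that("full segmentation matches phantom truth within a pixel", {
  for (seed in c(21, 22)) {
    sc <- makeCornealScene(snr = 20, seed = seed)
    seg <- segmentCornea(amplitudeImage(sc), segmentationConfig())
    expect_lte(mean(abs(anteriorPath(seg) - sc@truth$anterior)), 1)
    expect_lte(mean(abs(posteriorPath(seg) - sc@truth$posterior)), 1)
  }
  # without epithelium the gradient search takes over
  sc2 <- makeCornealScene(layout = list(epithelium = FALSE), snr = 20,
                          seed = 23)
  seg2 <- segmentCornea(amplitudeImage(sc2),
                        segmentationConfig("without_epithelium"))
  expect_lte(mean(abs(anteriorPath(seg2) - sc2@truth$anterior)), 1)
  expect_lte(mean(abs(posteriorPath(seg2) - sc2@truth$posterior)), 1)
})

test_that("segmentation is deterministic and fails on corneal-free scenes", {
  sc <- makeCornealScene(snr = 10, seed = 25)
  s1 <- segmentCornea(amplitudeImage(sc), segmentationConfig())
  s2 <- segmentCornea(amplitudeImage(sc), segmentationConfig())
  expect_identical(anteriorPath(s1), anteriorPath(s2))
  expect_identical(posteriorPath(s1), posteriorPath(s2))

  empty <- matrix(0, 200, 40)
  empty[15, ] <- 8; empty[185, ] <- 8   # walls only, no cornea
  expect_error(segmentCornea(empty, segmentationConfig()),
               class = "dvioct_segmentation_failure")
})

test_that("per-column accuracy holds across random scenes and SNRs", {
  set.seed(77)
  errs <- c()
  for (i in 1:20) {
    sc <- makeCornealScene(
      layout = list(curvaturePx = runif(1, 0, 12),
                    anteriorRow = sample(60:85, 1),
                    thicknessPx = sample(180:260, 1)),
      snr = sample(c(5, 10, 20, 50), 1), seed = 1000 + i)
    seg <- segmentCornea(amplitudeImage(sc), segmentationConfig())
    errs <- c(errs, abs(anteriorPath(seg) - sc@truth$anterior),
              abs(posteriorPath(seg) - sc@truth$posterior))
  }
  expect_gte(mean(errs <= 2), 0.95)
})
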