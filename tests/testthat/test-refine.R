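# Stage 3: filtering and overlap correction.

test_that("border-touching components are removed, interior ones kept", {
  m <- matrix(0L, 8, 8)
  m[1, 3:4] <- 1L          # touches row 1
  m[4:5, 4:5] <- 2L        # interior
  m[6:8, 7] <- 3L          # touches last row
  out <- removeBorderObjects(m)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_true(all(out[4:5, 4:5] == 1L))
})

test_that("border removal matches a four-border-line scan oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- labelComponents(randomBlobMask(15, 15, 0.35), 8)
    out <- removeBorderObjects(m)
    bad <- unique(c(m[1, ], m[15, ], m[, 1], m[, 15]))
    keptOrig <- setdiff(unique(as.vector(m)), c(0L, bad))
    expect_equal(max(out), length(keptOrig))
    expect_equal(sum(out > 0),
                 sum(m %in% keptOrig))
  }
})

test_that("fragment merging uses a strict size threshold", {
  m <- matrix(0L, 100, 100)            # 10,000 px; 0.1% = 10 px
  m[40:49, 40:59] <- 1L                # large comet (200 px)
  m[10:12, 10:12] <- 2L                # 9 px fragment: merged
  out <- mergeSmallFragments(m, 0.001)
  expect_equal(max(out), 1)
  expect_equal(out[11, 11], out[45, 50])

  m[10:12, 10:12] <- 0L
  m[10:14, 10:11] <- 2L                # exactly 10 px: kept
  out2 <- mergeSmallFragments(m, 0.001)
  expect_equal(max(out2), 2)
})

test_that("fragments merge into the closest large component", {
  m <- matrix(0L, 100, 100)
  m[10:19, 10:29] <- 1L                # comet A
  m[60:69, 60:79] <- 2L                # comet B
  m[50:52, 50:52] <- 3L                # fragment nearer to B
  out <- mergeSmallFragments(m, 0.001)
  # brute-force all pairwise pixel distances
  fr <- which(m == 3, arr.ind = TRUE)
  dA <- min(sqrt(outer(fr[, 1], which(m == 1, arr.ind = TRUE)[, 1], "-")^2 +
                 outer(fr[, 2], which(m == 1, arr.ind = TRUE)[, 2], "-")^2))
  dB <- min(sqrt(outer(fr[, 1], which(m == 2, arr.ind = TRUE)[, 1], "-")^2 +
                 outer(fr[, 2], which(m == 2, arr.ind = TRUE)[, 2], "-")^2))
  expect_lt(dB, dA)
  expect_equal(out[51, 51], out[65, 70])
  # with no large component at all, fragments are deleted
  m2 <- matrix(0L, 100, 100); m2[1:2, 1:2] <- 1L
  expect_equal(max(mergeSmallFragments(m2, 0.001)), 0)
})

test_that("distance transform matches the all-pairs oracle", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(distanceTransform(m)[3, 3], 1)

  m2 <- matrix(0L, 9, 9); m2[3:7, 3:7] <- 1L
  # center of a filled 5x5 square: nearest background pixel is 3 away
  # (one more than the distance to the object's own boundary pixel)
  expect_equal(distanceTransform(m2)[5, 5], 3)

  set.seed(32)
  for (rep in 1:8) {
    m3 <- randomBlobMask(12, 12, 0.55)
    expect_equal(distanceTransform(m3), oracleDistance(m3), tolerance = 1e-12)
  }
})

test_that("Haar smoothing: constants unchanged, level 1 is 2x2 block averaging", {
  m <- matrix(5.5, 8, 8)
  expect_equal(waveletSmooth(m, 2), m)

  set.seed(33)
  r <- matrix(runif(16, 0, 9), 4, 4)
  sm <- waveletSmooth(r, 1)
  # oracle: each non-overlapping 2x2 block replaced by its mean
  blk <- r
  for (i in c(1, 3)) for (j in c(1, 3)) {
    blk[i:(i + 1), j:(j + 1)] <- mean(r[i:(i + 1), j:(j + 1)])
  }
  expect_equal(sm, blk, tolerance = 1e-12)
  expect_error(waveletSmooth(matrix(1, 2, 2), 6), "too large")
})

test_that("Haar smoothing reduces the depth of a shallow pit", {
  r <- matrix(6, 8, 8)
  r[4, 5] <- 2  # one-pixel pit in a plateau
  sm <- waveletSmooth(r, 1)
  expect_gt(min(sm[3:5, 4:6]), min(r[3:5, 4:6]))
})

test_that("watershed floods one basin per regional maximum", {
  # single hump: one basin covering the parent
  mask <- matrix(1L, 6, 10)
  relief <- outer(3 - abs(3.5 - seq_len(6)), 5 - abs(5.5 - seq_len(10)) / 2)
  ws <- watershedSplit(relief, mask, tol = 0)
  expect_equal(max(ws), 1)
  expect_true(all(ws[mask == 1] == 1))

  # two equal humps separated by a saddle: split at the saddle column
  mask2 <- matrix(1L, 8, 16)
  x <- seq_len(16); y <- seq_len(8)
  relief2 <- outer(exp(-(y - 4.5)^2 / 6),
                   exp(-(x - 4)^2 / 8) + exp(-(x - 13)^2 / 8)) * 10
  ws2 <- watershedSplit(relief2, mask2, tol = 0)
  expect_equal(max(ws2), 2)
  expect_true(all(ws2[, 1:3] == 1))
  expect_true(all(ws2[, 14:16] == 2))

  # disjoint parents: basins never cross parent boundaries
  mask3 <- matrix(0L, 6, 10); mask3[2:5, 2:4] <- 1L; mask3[2:5, 7:9] <- 1L
  ws3 <- watershedSplit(distanceTransform(mask3), mask3, tol = 0)
  expect_gte(max(ws3), 2)
  expect_equal(sum(ws3 > 0), sum(mask3 > 0))
  expect_true(length(unique(ws3[mask3 == 1][1:12])) >= 1)
})

test_that("watershed and regional maxima match the exhaustive flooding oracle", {
  set.seed(34)
  for (rep in 1:6) {
    mask <- randomBlobMask(12, 12, 0.6)
    relief <- matrix(0, 12, 12)
    relief[mask == 1] <- sample(1:6, sum(mask), replace = TRUE)
    for (tol in c(0, 0.5)) {
      expect_equal(regionalMaxima(relief, mask, tol = tol),
                   oracleRegionalMaxima(relief, mask, tol = tol))
      expect_equal(watershedSplit(relief, mask, tol = tol),
                   oracleWatershed(relief, mask, tol = tol))
    }
  }
})

test_that("horizontal merging collapses stacked chunks and respects transitivity", {
  # identical column ranges, stacked vertically -> one segment
  m <- matrix(0L, 6, 8)
  m[1:3, 2:7] <- 1L; m[4:6, 2:7] <- 2L
  expect_equal(max(mergeHorizontal(m, 0.5)), 1)

  # side-by-side disjoint column ranges -> unchanged
  m2 <- matrix(0L, 6, 9)
  m2[2:5, 1:4] <- 1L; m2[2:5, 5:9] <- 2L
  expect_equal(max(mergeHorizontal(m2, 0.5)), 2)

  # three stacked fragments with chained overlaps -> single segment
  m3 <- matrix(0L, 9, 12)
  m3[1:3, 1:8] <- 1L; m3[4:6, 3:10] <- 2L; m3[7:9, 5:12] <- 3L
  out <- mergeHorizontal(m3, 0.5)
  expect_equal(max(out), 1)
  # union-find oracle on the pairwise overlap graph agrees
  expect_equal(length(unique(out[out > 0])), 1)
})

test_that("contour spectra rank circle > ellipse-like > star in low-frequency share", {
  disc <- function(r, n) {
    m <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if ((i - (n + 1) / 2)^2 + (j - (n + 1) / 2)^2 <= r^2) m[i, j] <- 1L
    }
    m
  }
  circ <- contourSpectrum(disc(20, 45))
  amps <- circ$amplitudes
  # the fundamental pair dominates; every other frequency is small
  pairShare <- (amps[1] + amps[length(amps)]) / sum(amps)
  expect_gt(pairShare, 0.9)  # digitized contour; parametric circle -> 1
  expect_lt(max(amps[2:(length(amps) - 1)]) / sum(amps), 0.05)

  ell <- matrix(0L, 25, 49)
  for (i in 1:25) for (j in 1:49) {
    if (((i - 13) / 10)^2 + ((j - 25) / 20)^2 <= 1) ell[i, j] <- 1L
  }
  se <- contourSpectrum(ell)
  ea <- se$amplitudes
  expect_gt((ea[1] + ea[length(ea)]) / sum(ea), 0.85)

  # point-symmetric 4-armed star: lower low-frequency dominance
  star <- matrix(0L, 41, 41)
  for (i in 1:41) for (j in 1:41) {
    dy <- i - 21; dx <- j - 21
    r <- sqrt(dx^2 + dy^2); a <- atan2(dy, dx)
    if (r <= 8 + 10 * abs(cos(2 * a))) star[i, j] <- 1L
  }
  ss <- contourSpectrum(star)
  expect_lt(ss$roundness, circ$roundness)
  expect_error(contourSpectrum(matrix(0L, 4, 4)), "empty")
  one <- matrix(0L, 4, 4); one[2, 2] <- 1L
  expect_error(contourSpectrum(one), "degenerate")
})

test_that("chunk validity combines roundness and relative area", {
  disc <- matrix(0L, 31, 31)
  for (i in 1:31) for (j in 1:31) {
    if ((i - 16)^2 + (j - 16)^2 <= 100) disc[i, j] <- 1L
  }
  parent <- matrix(1L, 31, 31)
  # circular chunk covering ~33% of its parent: valid
  expect_true(chunkIsValid(disc, parent, roundnessMin = 0.7,
                           areaRatioMin = 0.03))
  # tiny chunk (< 3% of parent): invalid regardless of shape
  small <- matrix(0L, 31, 31); small[14:17, 14:17] <- 1L
  expect_false(chunkIsValid(small, parent, roundnessMin = 0.7,
                            areaRatioMin = 0.03))
  # ragged elongated chunk with low low-frequency share: invalid
  zig <- matrix(0L, 31, 31)
  for (j in 3:29) zig[16 + round(6 * sin(j * 2)) + (-1:1), j] <- 1L
  sp <- contourSpectrum(zig)
  if (sp$roundness < 0.7) {
    expect_false(chunkIsValid(zig, parent, spectrum = sp,
                              roundnessMin = 0.7, areaRatioMin = 0.03))
  }
  expect_error(chunkIsValid(disc, matrix(0L, 31, 31)), "empty")
})

test_that("overlap correction separates touching comets and conserves pixels", {
  cfg <- cometConfig()
  # an isolated comet passes through pixel-identical
  sc1 <- composeScene(nComets = 1, overlapRate = 0, nDebris = 0, seed = 41,
                      size = NULL)
  res1 <- suppressWarnings(runPipeline(sceneImage(sc1), cfg))
  cfgNo <- cometConfig(overlapCorrection = FALSE)
  res1no <- suppressWarnings(runPipeline(sceneImage(sc1), cfgNo))
  expect_equal(nComets(res1), 1)
  expect_equal(labelMask(res1), labelMask(res1no))

  # two comets rendered touching -> two components near the true centroids
  set.seed(42)
  sc2 <- composeScene(nComets = 2, overlapRate = 0.5, nDebris = 0, seed = 42,
                      size = c(200, 300))
  res2 <- suppressWarnings(runPipeline(sceneImage(sc2), cfg))
  expect_equal(nComets(res2), 2)
  m <- centroidMatch(cbind(cometRecords(res2)$centroid_row,
                           cometRecords(res2)$centroid_col),
                     sc2@centroids, 15)
  expect_equal(m$tp, 2)

  # pixel conservation: no foreground is created
  img <- smoothImage(sceneImage(sc2), "median", 5)
  t <- chooseThreshold(img, cfg)
  labels <- mergeSmallFragments(removeBorderObjects(
    labelComponents(applyThreshold(img, t), 8)), 0.001)
  out <- correctOverlaps(labels, cfg)
  expect_true(all(labels[out > 0] > 0))
})
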