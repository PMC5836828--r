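# Stage 2: histogram, thresholds, labeling.

mkHist <- function(counts) {
  bins <- length(counts)
  structure(list(counts = as.integer(counts),
                 breaks = seq(0, 256, length.out = bins + 1),
                 left = (seq_len(bins) - 1) * 256 / bins),
            class = "GrayHistogram")
}

test_that("histogram conserves pixels and matches a per-pixel tally", {
  img <- matrix(c(0, 0, 255, 255), 2, 2)
  h <- grayHistogram(img, 256)
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 2)
  expect_equal(sum(h$counts), 4)

  set.seed(21)
  img2 <- matrix(runif(300, 0, 255), 15, 20)
  h2 <- grayHistogram(img2, 256)
  expect_equal(sum(h2$counts), 300)
  expect_equal(h2$counts, oracleHistogram(img2, 256))
  h3 <- grayHistogram(img2, 64)
  expect_equal(h3$counts, oracleHistogram(img2, 64))
  expect_error(grayHistogram(img2, 1), "bins")
})

test_that("first valley sits after the first peak, leftmost on plateaus", {
  # hand-scannable histogram: peaks at bins 3 and 7 (1-based), valley at 5
  t <- firstValleyThreshold(mkHist(c(0, 5, 9, 5, 1, 5, 9, 5, 0)),
                            smoothWindow = 1)
  expect_equal(attr(t, "bin"), 5)

  # plateau valley: leftmost plateau bin wins
  t2 <- firstValleyThreshold(mkHist(c(1, 9, 4, 2, 2, 2, 9, 1)),
                             smoothWindow = 1)
  expect_equal(attr(t2, "bin"), 4)

  # strictly decreasing counts: no valley
  expect_error(firstValleyThreshold(mkHist(9:1), smoothWindow = 1),
               class = "cometNoValley")
  # monotone increasing: no peak at all
  expect_error(firstValleyThreshold(mkHist(1:9), smoothWindow = 1),
               class = "cometNoValley")
})

test_that("bimodal Gaussian-shaped histograms give the between-peak minimum", {
  x <- 0:255
  counts <- round(4000 * exp(-(x - 10)^2 / 18) + 800 * exp(-(x - 200)^2 / 800))
  t <- firstValleyThreshold(mkHist(counts), smoothWindow = 5)
  # oracle: exhaustive scan of the smoothed counts between the two peaks
  sm <- as.numeric(stats::filter(c(rep(counts[1], 2), counts,
                                   rep(counts[256], 2)),
                                 rep(1 / 5, 5), sides = 2))[3:258]
  p1 <- which.max(sm[1:100]); p2 <- 100 + which.max(sm[101:256])
  valleyBin <- p1 + which.min(sm[p1:p2]) - 1
  expect_equal(attr(t, "bin"), valleyBin)
})

test_that("Otsu picks the smallest optimal split and flags degenerate input", {
  img <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  t <- otsuThreshold(grayHistogram(img))
  expect_equal(as.numeric(t), 10)
  expect_error(otsuThreshold(grayHistogram(matrix(40, 3, 3))),
               class = "cometDegenerate")
})

test_that("Otsu equals exhaustive between-class variance maximization", {
  set.seed(22)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 64, replace = TRUE,
                         prob = runif(256)^2), 8, 8)
    h <- grayHistogram(img, 256)
    t <- otsuThreshold(h)
    expect_equal(attr(t, "bin"), oracleOtsu(h$counts, h$left))
  }
})

test_that("thresholding keeps only pixels strictly above t", {
  img <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(sum(applyThreshold(img, 255)), 0)
  expect_equal(sum(applyThreshold(img, -1)), 64)
  t <- 127
  expect_equal(applyThreshold(img, t),
               matrix(as.integer(img > t), 8, 8))
  expect_equal(sum(applyThreshold(matrix(c(10, 10.5), 1, 2), 10)), 1)
})

test_that("connectivity 8 joins diagonals, connectivity 4 does not", {
  m <- matrix(0L, 2, 2); m[1, 1] <- 1L; m[2, 2] <- 1L
  expect_equal(max(labelComponents(m, 8)), 1)
  expect_equal(max(labelComponents(m, 4)), 2)
  expect_error(labelComponents(m, 6), "connectivity")
})

test_that("labeling matches a flood-fill oracle and is raster-deterministic", {
  set.seed(23)
  for (rep in 1:6) {
    m <- randomBlobMask(20, 20, 0.4)
    for (conn in c(4, 8)) {
      lab <- labelComponents(m, conn)
      ref <- oracleLabel(m, conn)
      # identical partitions
      expect_equal(max(lab), max(ref))
      for (k in seq_len(max(ref))) {
        expect_true(length(unique(lab[ref == k])) == 1)
      }
      # labels ordered by first raster (row-major) pixel
      firsts <- vapply(seq_len(max(lab)), function(k) {
        ij <- which(lab == k, arr.ind = TRUE)
        min((ij[, 1] - 1) * ncol(m) + ij[, 2])
      }, numeric(1))
      expect_equal(order(firsts), seq_len(max(lab)))
    }
  }
})

test_that("valley threshold never exceeds Otsu on scenes with a background peak", {
  for (seed in 1:3) {
    sc <- composeScene(nComets = 8, overlapRate = 0, nDebris = 4,
                       seed = seed, size = c(300, 420))
    h <- grayHistogram(smoothImage(sceneImage(sc), "median", 5))
    tv <- firstValleyThreshold(h, 5)
    to <- otsuThreshold(h)
    expect_lte(as.numeric(tv), as.numeric(to))
  }
})
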