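# Stage 4a: profile measurements and tail moments.

test_that("intensity profiles are masked per-column sums", {
  img <- matrix(0, 4, 6)
  mask <- matrix(0L, 4, 6)
  img[2, 3] <- 10; img[3, 3] <- 20
  mask[2:3, 3] <- 1L
  p <- intensityProfile(img, mask, 1)
  expect_equal(p$values, 30)
  expect_equal(p$colOrigin, 3)

  # rectangular comet of constant intensity c and height h
  img2 <- matrix(7, 5, 8); mask2 <- matrix(0L, 5, 8)
  mask2[2:4, 3:6] <- 1L
  p2 <- intensityProfile(img2, mask2, 1)
  expect_equal(p2$values, rep(21, 4))

  # random fixture vs direct masked column sums (other comets excluded)
  set.seed(51)
  img3 <- matrix(runif(48, 0, 255), 6, 8)
  mask3 <- matrix(0L, 6, 8)
  mask3[2:4, 2:5] <- 1L; mask3[5, 3:7] <- 2L
  p3 <- intensityProfile(img3, mask3, 1)
  direct <- vapply(2:5, function(j) sum(img3[2:4, j][mask3[2:4, j] == 1]),
                   numeric(1))
  expect_equal(p3$values, direct)
  expect_error(intensityProfile(img3, mask3, 9), "not present")
})

test_that("CPH is the leftmost profile argmax", {
  expect_equal(findCPH(c(1, 5, 3)), 2)
  expect_equal(findCPH(c(4, 4, 1)), 1)
  set.seed(52)
  for (rep in 1:10) {
    v <- runif(20, 0, 100)
    expect_equal(findCPH(v), which(v == max(v))[1])
  }
  expect_error(findCPH(c(0, 0, 0)), class = "cometDegenerate")
})

test_that("head radius is the distance to the first sub-threshold column", {
  expect_equal(headRadius(c(0, 10, 0), 2, 0.5), 1)
  # monotone profile: first value < 5 is at position 4 -> r = 3
  expect_equal(headRadius(c(10, 8, 6, 4), 1, 0.5), 3)
  # no drop before the end: r extends to the profile end
  expect_equal(headRadius(c(10, 9, 8, 7), 1, 0.5), 3)
  # discretized Gaussian, sigma 4, HT 0.5: continuous half-width 4.71 -> r = 5
  v <- exp(-(-12:12)^2 / (2 * 16))
  expect_equal(headRadius(v, 13, 0.5), 5)
  expect_error(headRadius(c(1, 2), 1, 0), "HT")
})

test_that("tail bounds, DNA fractions, CMT and inertia follow the hand example", {
  v <- c(0, 10, 6, 4, 2, 1, 0)
  cph <- findCPH(v)
  expect_equal(cph, 2)
  r <- headRadius(v, cph, 0.5)
  expect_equal(r, 2)  # first value < 5 right of the peak is 4
  tb <- tailBounds(v, cph, r)
  expect_equal(tb$tailStart, 4)
  expect_equal(tb$tailEnd, 6)
  expect_equal(tb$tailLength, 2)
  expect_equal(tb$tailCols, c(5, 6))
  da <- dnaAmounts(v, tb$tailCols)
  expect_equal(da$dna, 23)
  expect_equal(da$tdna, 3 / 23)
  cd <- cmtAndDistance(v, tb$tailCols, cph)
  expect_equal(cd$cmt, 16 / 3)
  expect_equal(cd$tailDistance, 10 / 3)
  expect_equal(momentOfInertia(v, tb$tailCols, cph, da$dna), 34 / 23)

  # empty tail: zero length, zero fraction, flagged CMT
  tb0 <- tailBounds(c(0, 10, 0), 2, 1)
  expect_equal(tb0$tailLength, 0)
  expect_equal(dnaAmounts(c(0, 10, 0), tb0$tailCols)$tdna, 0)
  cd0 <- cmtAndDistance(c(0, 10, 0), integer(0), 2)
  expect_true(cd0$flagged)
  expect_equal(cd0$tailDistance, 0)
  expect_equal(momentOfInertia(v, integer(0), 2, 23), 0)
  expect_error(dnaAmounts(c(0, 0), integer(0)), class = "cometDegenerate")
})

test_that("CMT degenerates correctly for single and uniform tails", {
  expect_equal(cmtAndDistance(c(0, 9, 0, 4), 4, 2)$cmt, 4)
  v <- c(0, 10, rep(2, 5))
  expect_equal(cmtAndDistance(v, 3:7, 2)$cmt, 5)  # midpoint by symmetry
})

test_that("tail moments reproduce the published worked values", {
  m1 <- tailMoments(0.7484, 35, 0)
  expect_equal(m1$extent, 26.19, tolerance = 0.02 / 26.19)
  m2 <- tailMoments(0.9560, 58, 28)
  expect_equal(m2$extent, 55.46, tolerance = 0.02 / 55.46)
  expect_equal(m2$olive, 26.77, tolerance = 0.02 / 26.77)
  m0 <- tailMoments(0, 12, 7)
  expect_equal(m0$extent, 0)
  expect_equal(m0$olive, 0)
  expect_error(tailMoments(1.2, 1, 1), "tdna")
})

test_that("records satisfy the definitional identities and bounds", {
  sc <- composeScene(nComets = 6, overlapRate = 0, nDebris = 2, seed = 53,
                     size = c(320, 460))
  res <- suppressWarnings(runPipeline(sceneImage(sc)))
  rec <- cometRecords(res)
  expect_gt(nrow(rec), 0)
  ok <- rec$flag != "degenerate"
  expect_true(all(rec$tdna[ok] >= 0 & rec$tdna[ok] <= 1))
  expect_true(all(rec$dna[ok] > 0))
  expect_equal(rec$extent_moment[ok], rec$tdna[ok] * rec$tail_length[ok])
  expect_equal(rec$olive_moment[ok], rec$tdna[ok] * rec$tail_distance[ok])
  expect_true(all(rec$head_radius[ok] >= 0))
  expect_true(all(rec$tail_length[ok] >= 0))
  # inertia >= tdna * (minimum tail-to-CPH distance)^2; the minimum gap is
  # head_radius + 1 columns by construction of the tail set
  gap <- (rec$head_radius[ok] + 1)^2
  hasTail <- rec$tail_length[ok] > 0
  expect_true(all(rec$inertia_moment[ok][hasTail] >=
                    (rec$tdna[ok] * gap)[hasTail] - 1e-9))
})

test_that("an all-head disc has zero tail and zero moments", {
  # with HT below the support floor, the head reaches the support edge and
  # no tail column remains
  sp <- cometSpec("normal", headSigma = 5, headPeak = 200, damage = 0,
                  tailLength = 0, tailDecay = 3)
  rc <- renderComet(sp, seed = 54, noise = FALSE,
                    config = cometConfig(headThreshold = 0.01))
  expect_equal(rc$truth$tail_length, 0)
  expect_equal(rc$truth$tdna, 0)
  expect_equal(rc$truth$extent_moment, 0)
  expect_equal(rc$truth$olive_moment, 0)
  expect_equal(rc$truth$inertia_moment, 0)

  # at the default half-max head threshold, an undamaged comet keeps only
  # the head-fringe baseline in the tail region
  rc2 <- renderComet(sp, seed = 54, noise = FALSE)
  expect_lt(rc2$truth$tdna, 0.15)
})

test_that("mirrored acquisitions give identical scalar records with tailDirection -x", {
  sp <- cometSpec("necrosis", headSigma = 4.5, headPeak = 210, damage = 0.5,
                  tailLength = 45, tailDecay = 4)
  rc <- renderComet(sp, seed = 55, noise = FALSE)
  img <- rc$noiseless; mask <- rc$supportMask
  imgM <- img[, rev(seq_len(ncol(img)))]
  maskM <- mask[, rev(seq_len(ncol(mask)))]
  a <- characterizeComet(img, mask, 1, cometConfig())
  b <- characterizeComet(imgM, maskM, 1, cometConfig(tailDirection = "-x"))
  for (f in c("tdna", "dna", "head_radius", "tail_length", "tail_distance",
              "extent_moment", "olive_moment", "inertia_moment")) {
    expect_equal(a[[f]], b[[f]], info = f)
  }
  # and the mirrored CPH reflects across the image
  expect_equal(a$cph - 1, ncol(img) - b$cph)
})

test_that("true TDNA increases with the damage parameter", {
  td <- vapply(c(0.1, 0.25, 0.4, 0.55, 0.7), function(d) {
    sp <- cometSpec("necrosis", headSigma = 4.5, headPeak = 200, damage = d,
                    tailLength = 40, tailDecay = 4)
    renderComet(sp, seed = 56, noise = FALSE)$truth$tdna
  }, numeric(1))
  expect_true(all(diff(td) > 0))
})

test_that("single-comet recovery lands near the generator truth", {
  cfg <- cometConfig()
  sp <- cometSpec("necrosis", headSigma = 4.5, headPeak = 200, damage = 0.5,
                  tailLength = 45, tailDecay = 4)
  sc <- composeScene(specs = list(sp), overlapRate = 0, nDebris = 0,
                     seed = 57, size = NULL)
  res <- suppressWarnings(runPipeline(sceneImage(sc), cfg))
  expect_equal(nComets(res), 1)
  expect_lt(abs(cometRecords(res)$tdna - cometRecords(sc)$tdna), 0.05)
})
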