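# Stage 4b: patches, HOG features, box ratio, classifiers.

test_that("patch preparation yields a 50x50 resize and its left half", {
  crop <- matrix(runif(10000, 0, 255), 100, 100)
  p <- preparePatches(crop)
  expect_equal(dim(p$full), c(50, 50))
  expect_equal(dim(p$leftHalf), c(50, 25))
  expect_equal(p$leftHalf, p$full[, 1:25])

  const <- matrix(9, 50, 50)
  expect_equal(preparePatches(const)$full, const)
  expect_error(preparePatches(matrix(numeric(0), 0, 0)), "empty")
})

test_that("HOG dimensions match the stated cell/block geometry", {
  expect_length(hogFeatures(matrix(runif(2500), 50, 50)), 900)
  expect_length(hogFeatures(matrix(runif(1250), 50, 25)), 360)
  expect_error(hogFeatures(matrix(1, 10, 10)), "too small")
})

test_that("HOG is zero on constants and invariant to intensity shifts", {
  expect_equal(hogFeatures(matrix(42, 50, 50)), rep(0, 900))
  set.seed(61)
  p <- matrix(runif(2500, 0, 200), 50, 50)
  expect_equal(hogFeatures(p), hogFeatures(p + 17), tolerance = 1e-9)
})

test_that("box ratio is width over height", {
  expect_equal(boxRatio(80, 40), 2)
  expect_equal(boxRatio(31, 31), 1)
  expect_error(boxRatio(10, 0), "height")
})

test_that("necrosis comets are wider relative to height than normal ones", {
  set.seed(62)
  br <- function(cl) {
    vapply(1:12, function(i) {
      rc <- renderComet(sampleCometSpec(cl), seed = 600 + i)
      ij <- which(rc$supportMask == 1, arr.ind = TRUE)
      boxRatio(diff(range(ij[, 2])) + 1, diff(range(ij[, 1])) + 1)
    }, numeric(1))
  }
  expect_gt(mean(br("necrosis")), mean(br("normal")))
})

test_that("feature vectors have the documented lengths per feature set", {
  crop <- matrix(runif(3600, 0, 255), 60, 60)
  expect_length(buildFeatureVector(crop, boxRatio = 1.4, "hog_full_box"), 901)
  expect_length(buildFeatureVector(crop, boxRatio = 1.4, "hog_left_box"), 361)
  expect_length(buildFeatureVector(crop, featureSet = "hog_full"), 900)
  expect_length(buildFeatureVector(crop, featureSet = "hog_left"), 360)
  expect_error(buildFeatureVector(crop, featureSet = "hog_full_box"),
               "boxRatio")
  expect_error(buildFeatureVector(crop, featureSet = "pca"), "arg")
})

test_that("all four classifiers separate the synthetic classes", {
  ts <- makeTrainingSet(nPerClass = 15, featureSet = "hog_left_box", seed = 63)
  expect_equal(dim(ts$features), c(45, 361))
  for (m in c("svm_linear", "nn_softmax", "adaboost", "cart")) {
    r <- trainAndEvaluate(ts$features, ts$labels, m, folds = 3, seed = 1,
                          nTrees = 25)
    expect_gte(r$testAccuracy, 0.6)
    expect_gte(r$trainAccuracy, r$testAccuracy - 0.2)
  }
})

test_that("cross-validation is reproducible and near chance on shuffled labels", {
  ts <- makeTrainingSet(nPerClass = 15, featureSet = "hog_left_box", seed = 64)
  a <- trainAndEvaluate(ts$features, ts$labels, "cart", folds = 3, seed = 9)
  b <- trainAndEvaluate(ts$features, ts$labels, "cart", folds = 3, seed = 9)
  expect_identical(a, b)

  set.seed(65)
  shuffled <- sample(ts$labels)
  r <- trainAndEvaluate(ts$features, shuffled, "cart", folds = 3, seed = 9)
  expect_lt(abs(r$testAccuracy - 1 / 3), 0.22)
  expect_error(trainAndEvaluate(ts$features, ts$labels, "cart", folds = 30),
               "per class")
})

test_that("classification plugs into the pipeline records", {
  ts <- makeTrainingSet(nPerClass = 12, featureSet = "hog_full_box", seed = 66)
  model <- fitClassifier(ts$features, ts$labels, "svm_linear")
  sc <- composeScene(nComets = 4, overlapRate = 0, nDebris = 0, seed = 67,
                     size = c(300, 420))
  res <- suppressWarnings(runPipeline(sceneImage(sc), model = model))
  rec <- cometRecords(res)
  expect_true(all(rec$class_label %in%
                    c("normal", "necrosis", "apoptosis")))
})
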