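# Stage 4b: damage-state classification (normal / necrosis / apoptosis).
#
# Features are histograms of oriented gradients (HOG) over a 50x50 resize
# of the comet crop and over its left half (25 columns x 50 rows; an
# apoptotic nucleus always sits in the left-half area), optionally with
# the box ratio (bbox width / height) appended to discriminate
# horizontally elongated types such as necrosis. With 9 unsigned
# orientation bins, 8x8-pixel cells and 2x2-cell blocks at 1-cell stride,
# the vectors have exactly 900 (50x50), 360 (25x50), 901 and 361 entries.

#' Resize a comet crop into classification patches
#'
#' @param crop numeric matrix (a masked bounding-box crop).
#' @return list with \code{full} (50 rows x 50 cols bilinear resize) and
#'   \code{leftHalf} (columns 1--25 of \code{full}).
#' @export
preparePatches <- function(crop) {
  if (!length(crop) || all(dim(crop) == 0)) stop("empty crop")
  full <- EBImage::imageData(EBImage::resize(crop, w = 50, h = 50,
                                             filter = "bilinear"))
  list(full = full, leftHalf = full[, 1:25, drop = FALSE])
}

#' Histogram-of-oriented-gradients features of a patch
#'
#' Central-difference gradients (replicate borders), 9 unsigned
#' orientation bins over [0, 180) with linear interpolation between
#' adjacent bin centers, 8x8-pixel cells, 2x2-cell blocks with 1-cell
#' stride and per-block L2 normalization (numeric floor). Output length is
#' \code{(cellsX - 1) * (cellsY - 1) * 36}: 900 for a 50x50 patch, 360 for
#' 25x50. Adding a constant to all pixels leaves the features unchanged.
#'
#' @param patch numeric matrix, at least 16 px per axis.
#' @return numeric feature vector.
#' @export
hogFeatures <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  cellsY <- nr %/% 8L; cellsX <- nc %/% 8L
  if (cellsY < 2L || cellsX < 2L)
    stop("patch too small for 8x8 cells with 2x2 blocks: ", nr, "x", nc)
  # gradients: x = columns, y = rows; replicate borders
  right <- patch[, c(2:nc, nc), drop = FALSE]
  left <- patch[, c(1, 1:(nc - 1)), drop = FALSE]
  down <- patch[c(2:nr, nr), , drop = FALSE]
  up <- patch[c(1, 1:(nr - 1)), , drop = FALSE]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180  # unsigned orientation
  # vote into 9 bins (centers 10, 30, ..., 170) with linear interpolation
  nb <- 9L; bw <- 180 / nb
  pos <- ang / bw - 0.5
  b0 <- floor(pos)
  w1 <- pos - b0
  b0 <- (b0 %% nb) + 1L
  b1 <- (b0 %% nb) + 1L
  # restrict to the cell-covered region
  rowsUsed <- seq_len(cellsY * 8L); colsUsed <- seq_len(cellsX * 8L)
  cellRow <- (rowsUsed - 1L) %/% 8L
  cellCol <- (colsUsed - 1L) %/% 8L
  cellId <- outer(cellRow, cellCol, function(a, b) a + cellsY * b) + 1L
  sub <- function(m) as.vector(m[rowsUsed, colsUsed, drop = FALSE])
  idx0 <- (sub(matrix(b0, nr, nc)) - 1L) * (cellsY * cellsX) +
    as.vector(cellId)
  idx1 <- (sub(matrix(b1, nr, nc)) - 1L) * (cellsY * cellsX) +
    as.vector(cellId)
  v0 <- sub(mag) * (1 - sub(matrix(w1, nr, nc)))
  v1 <- sub(mag) * sub(matrix(w1, nr, nc))
  hist <- numeric(nb * cellsY * cellsX)
  acc0 <- rowsum(c(v0, v1), c(idx0, idx1))
  hist[as.integer(rownames(acc0))] <- acc0[, 1]
  cellHist <- array(hist, dim = c(cellsY, cellsX, nb))
  # 2x2-cell blocks, stride 1, L2 norm
  out <- numeric((cellsY - 1L) * (cellsX - 1L) * 4L * nb)
  k <- 0L
  for (bx in seq_len(cellsX - 1L)) {
    for (by in seq_len(cellsY - 1L)) {
      block <- c(cellHist[by, bx, ], cellHist[by + 1L, bx, ],
                 cellHist[by, bx + 1L, ], cellHist[by + 1L, bx + 1L, ])
      nrm <- sqrt(sum(block^2) + 1e-12)
      out[k + seq_len(4L * nb)] <- if (nrm > 1e-6) block / nrm else 0
      k <- k + 4L * nb
    }
  }
  out
}

#' Box ratio of a comet bounding box
#'
#' Width divided by height; horizontally elongated comets (necrosis) have
#' large values.
#'
#' @param width bbox width in pixels (or a record row; see
#'   [characterizeComet()]).
#' @param height bbox height in pixels.
#' @return numeric.
#' @export
boxRatio <- function(width, height) {
  if (height <= 0) stop("height must be positive")
  width / height
}

.featureSets <- c("hog_left", "hog_left_box", "hog_full", "hog_full_box")
.featureLengths <- c(hog_left = 360L, hog_left_box = 361L,
                     hog_full = 900L, hog_full_box = 901L)

#' Build a classification feature vector
#'
#' @param crop masked comet crop (numeric matrix).
#' @param boxRatio the comet's bbox width/height ratio.
#' @param featureSet one of \code{"hog_left"} (360), \code{"hog_left_box"}
#'   (361), \code{"hog_full"} (900), \code{"hog_full_box"} (901).
#' @return numeric vector of the stated length.
#' @export
buildFeatureVector <- function(crop, boxRatio = NULL,
                               featureSet = c("hog_full_box", "hog_full",
                                              "hog_left_box", "hog_left")) {
  featureSet <- match.arg(featureSet)
  if (grepl("box$", featureSet) && is.null(boxRatio))
    stop("featureSet '", featureSet, "' requires boxRatio")
  p <- preparePatches(crop)
  v <- switch(featureSet,
              hog_left = hogFeatures(p$leftHalf),
              hog_left_box = c(hogFeatures(p$leftHalf), boxRatio),
              hog_full = hogFeatures(p$full),
              hog_full_box = c(hogFeatures(p$full), boxRatio))
  stopifnot(length(v) == .featureLengths[[featureSet]])
  v
}

.cometClasses <- c("normal", "necrosis", "apoptosis")

#' Fit a damage-state classifier
#'
#' \describe{
#'   \item{svm_linear}{three one-vs-one linear SVMs (normal vs necrosis,
#'     normal vs apoptosis, necrosis vs apoptosis) cascaded into a
#'     decision tree: the winner of the first comparison meets the
#'     remaining class.}
#'   \item{nn_softmax}{a single softmax layer (input and output layers
#'     only, three output nodes).}
#'   \item{adaboost}{SAMME boosting of depth-limited trees; 200 learners
#'     by default.}
#'   \item{cart}{a single classification tree with maximum depth 10.}
#' }
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor of class labels with levels
#'   \code{c("normal", "necrosis", "apoptosis")}.
#' @param method one of \code{"svm_linear"}, \code{"nn_softmax"},
#'   \code{"adaboost"}, \code{"cart"}.
#' @param nTrees AdaBoost learner count; default 200.
#' @param treeDepth AdaBoost weak-learner depth; default 2.
#' @return a model object for [predictClassifier()].
#' @export
fitClassifier <- function(x, y, method = c("svm_linear", "nn_softmax",
                                           "adaboost", "cart"),
                          nTrees = 200L, treeDepth = 2L) {
  method <- match.arg(method)
  y <- factor(y, levels = .cometClasses)
  if (any(table(y) == 0)) stop("every class must appear in the training data")
  x <- as.matrix(x)
  model <- switch(method,
    svm_linear = {
      pair <- function(a, b) {
        sel <- y %in% c(a, b)
        e1071::svm(x[sel, , drop = FALSE], droplevels(y[sel]),
                   kernel = "linear", scale = FALSE)
      }
      list(nn = pair("normal", "necrosis"),
           na = pair("normal", "apoptosis"),
           ca = pair("necrosis", "apoptosis"))
    },
    nn_softmax = {
      df <- data.frame(y = y, x)
      nnet::multinom(y ~ ., data = df, trace = FALSE,
                     MaxNWts = 100000, maxit = 200)
    },
    adaboost = .fitAdaboost(x, y, nTrees, treeDepth),
    cart = {
      df <- data.frame(y = y, x)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = 10,
                                                  cp = 0, xval = 0))
    })
  structure(list(method = method, model = model,
                 p = ncol(x)), class = "cometClassifier")
}

# SAMME AdaBoost with rpart weak learners
.fitAdaboost <- function(x, y, nTrees, treeDepth) {
  n <- nrow(x); K <- nlevels(y)
  df <- data.frame(y = y, x)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = treeDepth, cp = 0, xval = 0,
                               minsplit = 4)
  for (m in seq_len(nTrees)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-9) break
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

#' Predict damage states
#'
#' @param model a \code{"cometClassifier"} from [fitClassifier()].
#' @param x numeric feature matrix.
#' @return factor of predicted classes.
#' @export
predictClassifier <- function(model, x) {
  stopifnot(inherits(model, "cometClassifier"))
  x <- as.matrix(x)
  out <- switch(model$method,
    svm_linear = {
      m <- model$model
      p1 <- as.character(predict(m$nn, x))
      res <- character(nrow(x))
      for (i in seq_len(nrow(x))) {
        second <- if (p1[i] == "normal") m$na else m$ca
        res[i] <- as.character(predict(second, x[i, , drop = FALSE]))
      }
      res
    },
    nn_softmax = {
      df <- data.frame(x)
      as.character(stats::predict(model$model, newdata = df))
    },
    adaboost = {
      ab <- model$model
      df <- data.frame(x)
      score <- matrix(0, nrow(x), length(ab$levels),
                      dimnames = list(NULL, ab$levels))
      for (j in seq_along(ab$learners)) {
        pr <- as.character(stats::predict(ab$learners[[j]], df,
                                          type = "class"))
        score[cbind(seq_len(nrow(x)), match(pr, ab$levels))] <-
          score[cbind(seq_len(nrow(x)), match(pr, ab$levels))] +
          ab$alphas[j]
      }
      ab$levels[max.col(score, ties.method = "first")]
    },
    cart = {
      df <- data.frame(x)
      as.character(stats::predict(model$model, df, type = "class"))
    })
  factor(out, levels = .cometClasses)
}

#' Cross-validated training and evaluation of a classifier
#'
#' Stratified k-fold cross-validation; reports fold-averaged training and
#' test accuracy. All randomness (fold assignment) is controlled by
#' \code{seed}, so results are reproducible bit-for-bit.
#'
#' @param features numeric matrix, rows = samples.
#' @param labels class labels (coerced to the three comet classes).
#' @param classifier method name, see [fitClassifier()].
#' @param folds number of folds; default 10.
#' @param seed integer seed.
#' @param ... passed to [fitClassifier()] (e.g. \code{nTrees}).
#' @return list with \code{trainAccuracy} and \code{testAccuracy}.
#' @export
trainAndEvaluate <- function(features, labels,
                             classifier = c("svm_linear", "nn_softmax",
                                            "adaboost", "cart"),
                             folds = 10L, seed = 1L, ...) {
  classifier <- match.arg(classifier)
  y <- factor(labels, levels = .cometClasses)
  x <- as.matrix(features)
  folds <- as.integer(folds)
  if (min(table(y)) < folds)
    stop("need at least ", folds, " samples per class for ", folds,
         "-fold cross-validation")
  set.seed(seed)
  foldId <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldId[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  trainAcc <- testAcc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    fit <- fitClassifier(x[tr, , drop = FALSE], y[tr], classifier, ...)
    trainAcc[f] <- mean(predictClassifier(fit, x[tr, , drop = FALSE]) ==
                          y[tr])
    testAcc[f] <- mean(predictClassifier(fit, x[!tr, , drop = FALSE]) ==
                         y[!tr])
  }
  list(trainAccuracy = mean(trainAcc), testAccuracy = mean(testAcc))
}

#' Features and labels from synthetic comets
#'
#' Renders labeled single comets with the scene generator and extracts
#' classification features, giving a seeded, fully reproducible training
#' set (useful because no labeled reference comets ship with the package).
#'
#' @param nPerClass comets per class.
#' @param featureSet see [buildFeatureVector()].
#' @param seed integer seed.
#' @return list with \code{features} (matrix) and \code{labels} (factor).
#' @export
makeTrainingSet <- function(nPerClass = 60L, featureSet = "hog_full_box",
                            seed = 1L) {
  set.seed(seed)
  feats <- list(); labs <- character(0)
  for (cl in .cometClasses) {
    for (i in seq_len(nPerClass)) {
      spec <- sampleCometSpec(cl)
      rc <- renderComet(spec, seed = sample.int(2^30, 1))
      crop <- rc$patch
      crop[rc$supportMask == 0] <- 0
      br <- boxRatio(ncol(crop), nrow(crop))
      feats[[length(feats) + 1L]] <-
        buildFeatureVector(crop, boxRatio = br, featureSet = featureSet)
      labs <- c(labs, cl)
    }
  }
  list(features = do.call(rbind, feats),
       labels = factor(labs, levels = .cometClasses))
}
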