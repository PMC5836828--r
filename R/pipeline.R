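# Orchestration: smoothing -> first-valley binarization -> labeling ->
# border/fragment filtering -> overlap correction -> characterization
# (-> optional classification).

#' Run the full comet analysis pipeline on one image
#'
#' @param image a file path (PNG/TIFF) or a numeric matrix on the 0--255
#'   scale.
#' @param config a [CometConfig-class].
#' @param model optional \code{"cometClassifier"} from [fitClassifier()];
#'   when supplied, each record's \code{class_label} is predicted from its
#'   crop, otherwise it stays \code{"unclassified"}.
#' @param featureSet feature set for classification; see
#'   [buildFeatureVector()].
#' @param outputDir optional directory; when given, writes
#'   \code{records.csv}, \code{mask.tif} (16-bit label mask) and one
#'   masked crop PNG per comet.
#' @param verbose log per-stage comet counts with [message()].
#' @return a [CometResult-class].
#' @examples
#' sc <- composeScene(nComets = 3, overlapRate = 0, nDebris = 2, seed = 4,
#'                    size = c(200, 300))
#' res <- runPipeline(sceneImage(sc))
#' nComets(res)
#' @export
runPipeline <- function(image, config = cometConfig(), model = NULL,
                        featureSet = "hog_full_box", outputDir = NULL,
                        verbose = FALSE) {
  img <- if (is.character(image)) loadImage(image, config@grayMode) else image
  stopifnot(is.matrix(img))
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- character(0); counts <- integer(0)
  logStage <- function(stage, k) {
    stages <<- c(stages, stage); counts <<- c(counts, k)
    say("%-18s: %d object(s)", stage, k)
  }

  sm <- if (config@smoothingMethod == "none") img else
    smoothImage(img, config@smoothingMethod, config@smoothingWindow)
  # a constant (blank) image has no threshold; everything is background
  t <- tryCatch(chooseThreshold(sm, config),
                cometDegenerate = function(e) {
                  v <- max(sm)
                  attr(v, "method") <- "degenerate"
                  v
                })
  say("threshold          : %.2f (%s)", as.numeric(t), attr(t, "method"))
  binary <- applyThreshold(sm, t)
  labels <- labelComponents(binary, 8L)
  logStage("candidates", max(labels))
  labels <- removeBorderObjects(labels)
  logStage("border-filtered", max(labels))
  labels <- mergeSmallFragments(labels, config@smallFragmentFraction)
  logStage("fragment-merged", max(labels))
  if (config@overlapCorrection) {
    labels <- correctOverlaps(labels, config)
    logStage("overlap-corrected", max(labels))
  }

  meas <- sm
  if (config@backgroundSubtract) {
    bg <- stats::median(sm[labels == 0])
    meas <- pmax(sm - bg, 0)
  }
  n <- max(labels)
  records <- if (n == 0) emptyRecords() else
    do.call(rbind, lapply(seq_len(n), function(id)
      characterizeComet(meas, labels, id, config)))
  logStage("characterized", n)

  if (!is.null(model) && n > 0) {
    feats <- do.call(rbind, lapply(seq_len(n), function(id) {
      crop <- cropComet(meas, labels, id)
      buildFeatureVector(crop, boxRatio = records$box_ratio[id],
                         featureSet = featureSet)
    }))
    records$class_label <- as.character(predictClassifier(model, feats))
  }

  res <- new("CometResult", records = records,
             mask = labels, image = sm, config = config,
             stageLog = data.frame(stage = stages, objects = counts,
                                   stringsAsFactors = FALSE))
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeRecords(records, file.path(outputDir, "records.csv"))
    writeMask(labels, file.path(outputDir, "mask.tif"))
    for (id in seq_len(n)) {
      crop <- cropComet(sm, labels, id)
      png::writePNG(pmin(pmax(crop / 255, 0), 1),
                    file.path(outputDir, sprintf("comet_%03d.png", id)))
    }
  }
  res
}

#' Run the pipeline over a directory of images
#'
#' Processes every PNG/TIFF in \code{dir} independently; per-image errors
#' are recorded in the summary, never fatal for the batch.
#'
#' @param dir directory of images.
#' @param config a [CometConfig-class].
#' @param pattern filename regex; default PNG/TIFF extensions.
#' @param ... passed to [runPipeline()].
#' @return list with \code{results} (named list of [CometResult-class] or
#'   NULL for failures), \code{summary} (per-image data.frame with comet
#'   count, mean TDNA and status) and \code{records} (combined table with
#'   an \code{image} column).
#' @export
runBatch <- function(dir, config = cometConfig(),
                     pattern = "\\.(png|tif|tiff)$", ...) {
  files <- list.files(dir, pattern = pattern, ignore.case = TRUE,
                      full.names = TRUE)
  results <- stats::setNames(vector("list", length(files)), basename(files))
  rows <- list(); allRec <- list()
  for (f in files) {
    res <- tryCatch(runPipeline(f, config, ...), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[f]] <- data.frame(image = basename(f), n_comets = NA_integer_,
                              mean_tdna = NA_real_, status = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      results[[basename(f)]] <- res
      rec <- cometRecords(res)
      rows[[f]] <- data.frame(image = basename(f), n_comets = nrow(rec),
                              mean_tdna = if (nrow(rec)) mean(rec$tdna) else NA_real_,
                              status = "ok", stringsAsFactors = FALSE)
      if (nrow(rec)) {
        rec$image <- basename(f)
        allRec[[f]] <- rec
      }
    }
  }
  list(results = results,
       summary = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                 else data.frame(image = character(0), n_comets = integer(0),
                                 mean_tdna = numeric(0), status = character(0)),
       records = if (length(allRec)) do.call(rbind, c(allRec, list(make.row.names = FALSE)))
                 else cbind(emptyRecords(), image = character(0)))
}
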