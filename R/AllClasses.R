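#' @useDynLib CometKit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Pipeline configuration
#'
#' An S4 container for every tunable parameter of the comet analysis
#' pipeline. All stages read their settings from a single \code{CometConfig}
#' object, so a configuration plus a seed fully determines the output.
#'
#' Images are plain numeric matrices indexed \code{[row, col]} (1-based,
#' as usual in R), intensities on the 0--255 scale with fractional values
#' allowed after smoothing. Bounding boxes are closed integer ranges
#' \code{(rowMin, colMin, rowMax, colMax)}. The electrophoresis direction
#' (the direction tails extend) is \code{+x}, i.e. increasing column index,
#' by default; \code{tailDirection = "-x"} mirrors the analysis for
#' acquisitions with reversed orientation.
#'
#' @slot smoothingMethod character; \code{"median"}, \code{"mean"} or
#'   \code{"none"}.
#' @slot smoothingWindow odd integer, side of the smoothing window (px).
#' @slot grayMode character; how RGB input collapses to one channel:
#'   \code{"luminance"} (0.299R + 0.587G + 0.114B) or a single channel
#'   \code{"red"}, \code{"green"}, \code{"blue"} (SYBR-green stains are
#'   effectively monochrome in the green channel).
#' @slot histogramBins integer, number of gray-level histogram bins.
#' @slot histogramSmoothWindow odd integer, moving-average window applied to
#'   histogram counts before the first-valley search.
#' @slot thresholdMethod character; \code{"valley"} (first histogram valley,
#'   falling back to Otsu when no valley exists) or \code{"otsu"}.
#' @slot headThreshold fraction in (0, 1]; the head threshold HT, the
#'   fraction of the peak profile intensity that delimits the head radius.
#' @slot smallFragmentFraction fraction; components smaller than this
#'   fraction of the image area are merged into the closest large component.
#' @slot roundnessMin fraction; minimum share of the two lowest-frequency
#'   Fourier amplitudes for a chunk to count as a plausible cell.
#' @slot areaRatioMin fraction; minimum chunk area relative to its parent
#'   mask.
#' @slot horizontalOverlapMin fraction; minimum column-range overlap
#'   (relative to the smaller chunk) for merging vertically stacked chunks.
#' @slot waveletLevel integer; Haar smoothing depth for the distance relief.
#' @slot matchRadius numeric; centroid match radius (px) for evaluation.
#' @slot tailDirection character; \code{"+x"} or \code{"-x"}.
#' @slot overlapCorrection logical; run the overlap-correction stage.
#' @slot backgroundSubtract logical; subtract the estimated background
#'   level (median of background pixels) before characterization.
#' @slot seed integer; base seed for all stochastic components.
#'
#' @seealso [cometConfig()] for the user-facing constructor.
#' @export
setClass("CometConfig",
  representation(
    smoothingMethod = "character",
    smoothingWindow = "integer",
    grayMode = "character",
    histogramBins = "integer",
    histogramSmoothWindow = "integer",
    thresholdMethod = "character",
    headThreshold = "numeric",
    smallFragmentFraction = "numeric",
    roundnessMin = "numeric",
    areaRatioMin = "numeric",
    horizontalOverlapMin = "numeric",
    waveletLevel = "integer",
    matchRadius = "numeric",
    tailDirection = "character",
    overlapCorrection = "logical",
    backgroundSubtract = "logical",
    seed = "integer"
  )
)

setValidity("CometConfig", function(object) {
  msg <- character()
  oddpos <- function(w) length(w) == 1L && !is.na(w) && w >= 1L && w %% 2L == 1L
  frac01 <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!object@smoothingMethod %in% c("median", "mean", "none"))
    msg <- c(msg, "smoothingMethod must be 'median', 'mean' or 'none'")
  if (!oddpos(object@smoothingWindow))
    msg <- c(msg, "smoothingWindow must be an odd positive integer")
  if (!object@grayMode %in% c("luminance", "red", "green", "blue"))
    msg <- c(msg, "grayMode must be 'luminance', 'red', 'green' or 'blue'")
  if (object@histogramBins < 2L)
    msg <- c(msg, "histogramBins must be >= 2")
  if (!oddpos(object@histogramSmoothWindow))
    msg <- c(msg, "histogramSmoothWindow must be an odd positive integer")
  if (!object@thresholdMethod %in% c("valley", "otsu"))
    msg <- c(msg, "thresholdMethod must be 'valley' or 'otsu'")
  if (!(object@headThreshold > 0 && object@headThreshold <= 1))
    msg <- c(msg, "headThreshold must lie in (0, 1]")
  for (s in c("smallFragmentFraction", "roundnessMin", "areaRatioMin",
              "horizontalOverlapMin")) {
    if (!frac01(slot(object, s))) msg <- c(msg, paste(s, "must lie in [0, 1]"))
  }
  if (object@waveletLevel < 1L)
    msg <- c(msg, "waveletLevel must be >= 1")
  if (!(object@matchRadius > 0))
    msg <- c(msg, "matchRadius must be positive")
  if (!object@tailDirection %in% c("+x", "-x"))
    msg <- c(msg, "tailDirection must be '+x' or '-x'")
  if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' Returns a validated [CometConfig-class] object. Defaults follow the
#' published method where it states a value (0.1\% small-fragment threshold,
#' 70\% Fourier roundness, 3\% area ratio, 15 px centroid match radius) and
#' documented repository choices elsewhere (see the package vignette).
#'
#' @param smoothingMethod "median" (default), "mean" or "none".
#' @param smoothingWindow odd window side in pixels; default 5.
#' @param grayMode RGB collapse mode; default "luminance".
#' @param histogramBins histogram bins; default 256 (8-bit input).
#' @param histogramSmoothWindow moving-average window for histogram counts;
#'   default 5.
#' @param thresholdMethod "valley" (default) or "otsu".
#' @param headThreshold the head threshold HT, a user-set fraction of the
#'   profile peak; default 0.5 (half-maximum head boundary), see the
#'   vignette for the rationale.
#' @param smallFragmentFraction default 0.001 (0.1\% of image pixels).
#' @param roundnessMin default 0.70.
#' @param areaRatioMin default 0.03.
#' @param horizontalOverlapMin default 0.5.
#' @param waveletLevel Haar smoothing depth; default 2.
#' @param matchRadius default 15 px.
#' @param tailDirection "+x" (default) or "-x".
#' @param overlapCorrection logical, default TRUE.
#' @param backgroundSubtract logical, default TRUE.
#' @param seed integer seed, default 1.
#' @return A \code{CometConfig} object.
#' @examples
#' cfg <- cometConfig(headThreshold = 0.2)
#' cfg
#' @export
cometConfig <- function(smoothingMethod = "median",
                        smoothingWindow = 5L,
                        grayMode = "luminance",
                        histogramBins = 256L,
                        histogramSmoothWindow = 5L,
                        thresholdMethod = "valley",
                        headThreshold = 0.5,
                        smallFragmentFraction = 0.001,
                        roundnessMin = 0.70,
                        areaRatioMin = 0.03,
                        horizontalOverlapMin = 0.5,
                        waveletLevel = 2L,
                        matchRadius = 15,
                        tailDirection = "+x",
                        overlapCorrection = TRUE,
                        backgroundSubtract = TRUE,
                        seed = 1L) {
  new("CometConfig",
      smoothingMethod = smoothingMethod,
      smoothingWindow = as.integer(smoothingWindow),
      grayMode = grayMode,
      histogramBins = as.integer(histogramBins),
      histogramSmoothWindow = as.integer(histogramSmoothWindow),
      thresholdMethod = thresholdMethod,
      headThreshold = headThreshold,
      smallFragmentFraction = smallFragmentFraction,
      roundnessMin = roundnessMin,
      areaRatioMin = areaRatioMin,
      horizontalOverlapMin = horizontalOverlapMin,
      waveletLevel = as.integer(waveletLevel),
      matchRadius = matchRadius,
      tailDirection = tailDirection,
      overlapCorrection = overlapCorrection,
      backgroundSubtract = backgroundSubtract,
      seed = as.integer(seed))
}

#' Result of a pipeline run
#'
#' Holds the per-comet characterization table, the final label mask, the
#' preprocessed image the measurements were taken on, the configuration and
#' a per-stage object-count log.
#'
#' @slot records data.frame, one row per retained comet (see
#'   [characterizeComet()] for the columns).
#' @slot mask integer matrix, final label mask (0 = background).
#' @slot image numeric matrix, the smoothed image used for measurement.
#' @slot config the [CometConfig-class] used.
#' @slot stageLog data.frame with columns \code{stage} and \code{objects},
#'   the comet-candidate count after each pipeline stage.
#' @export
setClass("CometResult",
  representation(
    records = "data.frame",
    mask = "matrix",
    image = "matrix",
    config = "CometConfig",
    stageLog = "data.frame"
  )
)

setValidity("CometResult", function(object) {
  n <- nrow(object@records)
  k <- length(setdiff(unique(as.vector(object@mask)), 0L))
  if (n != k) return(sprintf("records (%d) and mask labels (%d) disagree", n, k))
  TRUE
})

#' Synthetic comet scene with ground truth
#'
#' Produced by [composeScene()]. The truth mask assigns each pixel of the
#' noiseless render to the comet contributing the most intensity there;
#' truth records are computed from the noiseless generative model by the
#' same tail-moment definitions the measurement stage uses.
#'
#' @slot image numeric matrix, the rendered noisy scene (0--255).
#' @slot masks integer matrix, per-comet ground-truth label mask.
#' @slot centroids numeric matrix with columns \code{row}, \code{col};
#'   intensity-weighted centroids of the noiseless comets.
#' @slot specs data.frame of generative parameters, one row per comet.
#' @slot records data.frame of true characterization records.
#' @export
setClass("CometScene",
  representation(
    image = "matrix",
    masks = "matrix",
    centroids = "matrix",
    specs = "data.frame",
    records = "data.frame"
  )
)

setValidity("CometScene", function(object) {
  n <- nrow(object@specs)
  if (nrow(object@centroids) != n || nrow(object@records) != n)
    return("specs, centroids and records must have one entry per comet")
  TRUE
})

#' @rdname cometRecords
#' @export
setGeneric("cometRecords", function(x) standardGeneric("cometRecords"))

#' @rdname labelMask
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))

#' @rdname nComets
#' @export
setGeneric("nComets", function(x) standardGeneric("nComets"))

#' Extract the per-comet record table
#'
#' @param x a [CometResult-class] or [CometScene-class].
#' @return A data.frame with one row per comet. For a \code{CometScene}
#'   these are the ground-truth records.
#' @export
setMethod("cometRecords", "CometResult", function(x) x@records)

#' @rdname cometRecords
#' @export
setMethod("cometRecords", "CometScene", function(x) x@records)

#' Extract the label mask
#'
#' @param x a [CometResult-class] or [CometScene-class].
#' @return Integer matrix; 0 is background, k > 0 is comet k.
#' @export
setMethod("labelMask", "CometResult", function(x) x@mask)

#' @rdname labelMask
#' @export
setMethod("labelMask", "CometScene", function(x) x@masks)

#' Number of comets
#'
#' @param x a [CometResult-class] or [CometScene-class].
#' @return Integer count of comets.
#' @export
setMethod("nComets", "CometResult", function(x) nrow(x@records))

#' @rdname nComets
#' @export
setMethod("nComets", "CometScene", function(x) nrow(x@specs))

#' @rdname pipelineLog
#' @export
setGeneric("pipelineLog", function(x) standardGeneric("pipelineLog"))

#' Per-stage object counts of a pipeline run
#'
#' @param x a [CometResult-class].
#' @return data.frame with columns \code{stage}, \code{objects}.
#' @export
setMethod("pipelineLog", "CometResult", function(x) x@stageLog)

#' @rdname sceneImage
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' Rendered image of a synthetic scene
#'
#' @param x a [CometScene-class].
#' @return Numeric matrix on the 0--255 scale.
#' @export
setMethod("sceneImage", "CometScene", function(x) x@image)

setMethod("show", "CometConfig", function(object) {
  cat("CometConfig\n")
  cat(sprintf("  smoothing      : %s, window %d\n",
              object@smoothingMethod, object@smoothingWindow))
  cat(sprintf("  threshold      : %s (bins %d, histogram smooth %d)\n",
              object@thresholdMethod, object@histogramBins,
              object@histogramSmoothWindow))
  cat(sprintf("  head threshold : %.3g\n", object@headThreshold))
  cat(sprintf("  filtering      : fragments < %.3g of pixels; roundness >= %.2f; area >= %.2f\n",
              object@smallFragmentFraction, object@roundnessMin,
              object@areaRatioMin))
  cat(sprintf("  overlap corr.  : %s (wavelet level %d, horiz. merge %.2f)\n",
              if (object@overlapCorrection) "on" else "off",
              object@waveletLevel, object@horizontalOverlapMin))
  cat(sprintf("  tail direction : %s; seed %d\n",
              object@tailDirection, object@seed))
  invisible(object)
})

setMethod("show", "CometResult", function(object) {
  cat(sprintf("CometResult: %d comet(s) on a %d x %d image\n",
              nrow(object@records), nrow(object@image), ncol(object@image)))
  if (nrow(object@stageLog)) {
    cat("  stages: ",
        paste(sprintf("%s=%d", object@stageLog$stage, object@stageLog$objects),
              collapse = " -> "), "\n", sep = "")
  }
  if (nrow(object@records)) {
    td <- object@records$tdna
    cat(sprintf("  TDNA: mean %.3f, range [%.3f, %.3f]\n",
                mean(td), min(td), max(td)))
    cl <- table(object@records$class_label)
    cat("  classes: ", paste(names(cl), as.integer(cl), sep = ":",
                             collapse = " "), "\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "CometScene", function(object) {
  cat(sprintf("CometScene: %d comet(s), %d x %d px\n",
              nrow(object@specs), nrow(object@image), ncol(object@image)))
  if (nrow(object@specs)) {
    cl <- table(object@specs$class_label)
    cat("  classes: ", paste(names(cl), as.integer(cl), sep = ":",
                             collapse = " "), "\n", sep = "")
    cat(sprintf("  true TDNA: mean %.3f\n", mean(object@records$tdna)))
  }
  invisible(object)
})
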