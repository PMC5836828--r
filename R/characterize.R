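# Stage 4a: per-comet measurement.
#
# The comet model is one-dimensional in x (the electrophoresis direction):
# all head/tail geometry is defined on the per-column integrated intensity
# profile. Treating intensity as mass turns classical mechanics
# definitions (center of mass, moment of inertia) into damage parameters:
#
#   DNA   = sum_{x in comet} I(x)
#   TDNA  = (1/DNA) sum_{x in tail} I(x)
#   extent moment     = TDNA * tail length
#   Olive moment      = TDNA * tail distance           (CMT - CPH)
#   moment of inertia = (1/DNA) sum_{x in tail} I(x) (CPH - x)^2

#' Integrated intensity profile of one comet
#'
#' Column sums of the comet's own pixels only; background and other comets
#' are excluded by the label mask.
#'
#' @param img numeric matrix.
#' @param mask integer label matrix of the same shape.
#' @param id comet label.
#' @return object of class \code{"IntensityProfile"}: list with
#'   \code{values} (per-column sums across the comet's bounding box) and
#'   \code{colOrigin} (absolute column of the first entry).
#' @export
intensityProfile <- function(img, mask, id) {
  stopifnot(all(dim(img) == dim(mask)))
  sel <- mask == id
  if (!any(sel)) stop("label ", id, " not present in mask")
  cc <- which(colSums(sel) > 0)
  c0 <- min(cc); c1 <- max(cc)
  vals <- vapply(c0:c1, function(j) sum(img[sel[, j], j]), numeric(1))
  structure(list(values = as.numeric(vals), colOrigin = c0),
            class = "IntensityProfile")
}

#' Center position of head (CPH)
#'
#' The peak position of the intensity profile; ties break to the leftmost
#' column.
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @return 1-based index of the peak within the profile.
#' @export
findCPH <- function(profile) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  if (!length(v)) stop("empty profile")
  if (all(v <= 0)) stop(structure(
    class = c("cometDegenerate", "error", "condition"),
    list(message = "all-zero profile: degenerate comet", call = sys.call())))
  which.max(v)  # first maximum = leftmost tie
}

#' Head radius from the head threshold HT
#'
#' The head's right boundary is the first column right of the CPH whose
#' profile value drops below \code{HT} times the peak value; the head
#' radius r is its distance from the CPH. If the profile never drops below
#' that level, r extends to the profile end.
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @param cph index from [findCPH()].
#' @param HT head threshold, a fraction in (0, 1].
#' @return head radius in pixels (integer >= 0).
#' @export
headRadius <- function(profile, cph, HT = 0.1) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  if (!(HT > 0 && HT <= 1)) stop("HT must lie in (0, 1]")
  if (cph < 1 || cph > length(v)) stop("cph out of range")
  lim <- HT * v[cph]
  if (cph == length(v)) return(0L)
  after <- v[(cph + 1L):length(v)]
  hit <- which(after < lim)
  if (length(hit)) hit[1] else length(v) - cph
}

#' Tail bounds on the profile
#'
#' The tail stretches from the right end of the head (CPH + r) to the last
#' column where the intensity is still positive; the span between these is
#' the tail length (floored at zero).
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @param cph head peak index.
#' @param r head radius.
#' @return list with \code{tailStart} (= cph + r), \code{tailEnd} (last
#'   positive column), \code{tailLength} and \code{tailCols} (indices in
#'   \code{(tailStart, tailEnd]}; empty when the tail has zero length).
#' @export
tailBounds <- function(profile, cph, r) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  tailStart <- cph + r
  if (tailStart > length(v)) tailStart <- length(v)
  pos <- which(v > 0)
  tailEnd <- if (length(pos)) max(pos) else tailStart
  len <- max(0L, tailEnd - tailStart)
  cols <- if (len > 0) seq(tailStart + 1L, tailEnd) else integer(0)
  list(tailStart = tailStart, tailEnd = tailEnd, tailLength = len,
       tailCols = cols)
}

#' Total and tail DNA amounts
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @param tailCols tail column indices from [tailBounds()].
#' @return list with \code{dna} (total summed intensity) and \code{tdna}
#'   (tail fraction, in \code{[0, 1]}).
#' @export
dnaAmounts <- function(profile, tailCols) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  dna <- sum(v)
  if (dna <= 0) stop(structure(
    class = c("cometDegenerate", "error", "condition"),
    list(message = "zero total DNA: degenerate comet", call = sys.call())))
  list(dna = dna, tdna = sum(v[tailCols]) / dna)
}

#' Extent and Olive tail moments
#'
#' \code{extent = TDNA * tail length}; \code{olive = TDNA * tail
#' distance}. TDNA enters as a fraction and lengths in pixels, matching
#' the convention under which a comet with TDNA 74.84\% and a 35 px tail
#' has extent moment 26.19.
#'
#' @param tdna tail DNA fraction in \code{[0, 1]}.
#' @param tailLength tail length in pixels.
#' @param tailDistance CMT - CPH in pixels.
#' @return list with \code{extent} and \code{olive}.
#' @examples
#' tailMoments(0.7484, 35, 28)
#' @export
tailMoments <- function(tdna, tailLength, tailDistance) {
  if (tdna < 0 || tdna > 1) stop("tdna must lie in [0, 1]")
  list(extent = tdna * tailLength, olive = tdna * tailDistance)
}

#' Center of mass of tail (CMT) and tail distance
#'
#' CMT is the intensity-weighted mean column over the tail; tail distance
#' is CMT - CPH. For an empty tail the distance is 0 and the CMT is
#' undefined (returned as NA with \code{flagged = TRUE}).
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @param tailCols tail column indices.
#' @param cph head peak index.
#' @return list with \code{cmt}, \code{tailDistance}, \code{flagged}.
#' @export
cmtAndDistance <- function(profile, tailCols, cph) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  mass <- sum(v[tailCols])
  if (!length(tailCols) || mass <= 0)
    return(list(cmt = NA_real_, tailDistance = 0, flagged = TRUE))
  cmt <- sum(tailCols * v[tailCols]) / mass
  list(cmt = cmt, tailDistance = cmt - cph, flagged = FALSE)
}

#' Moment of inertia of the tail
#'
#' \eqn{(1/DNA) \sum_{x \in tail} I(x) (CPH - x)^2}, in squared pixels.
#'
#' @param profile an \code{"IntensityProfile"} or numeric vector.
#' @param tailCols tail column indices.
#' @param cph head peak index.
#' @param dna total DNA.
#' @return numeric.
#' @export
momentOfInertia <- function(profile, tailCols, cph, dna) {
  v <- if (inherits(profile, "IntensityProfile")) profile$values else profile
  if (dna <= 0) stop("dna must be positive")
  if (!length(tailCols)) return(0)
  sum(v[tailCols] * (cph - tailCols)^2) / dna
}

#' Characterize one comet
#'
#' Composes the profile-based measurements into a one-row record:
#' bounding box, intensity-weighted centroid, CPH, head radius, tail
#' length/distance, DNA, TDNA, the three tail moments, box ratio and
#' area. With \code{tailDirection = "-x"} the profile is mirrored before
#' measurement, so a mirrored acquisition yields the same scalar record.
#' Degenerate comets (zero DNA) are reported with a flag, not dropped.
#'
#' @param img numeric matrix (typically the smoothed image).
#' @param mask integer label matrix.
#' @param id comet label.
#' @param config a [CometConfig-class].
#' @return one-row data.frame with the canonical record columns.
#' @export
characterizeComet <- function(img, mask, id, config = cometConfig()) {
  sel <- mask == id
  if (!any(sel)) stop("label ", id, " not present in mask")
  ij <- which(sel, arr.ind = TRUE)
  w <- img[sel]
  bbox <- c(min(ij[, 1]), min(ij[, 2]), max(ij[, 1]), max(ij[, 2]))
  area <- nrow(ij)
  height <- bbox[3] - bbox[1] + 1L
  width <- bbox[4] - bbox[2] + 1L
  centroid <- if (sum(w) > 0) {
    c(sum(ij[, 1] * w), sum(ij[, 2] * w)) / sum(w)
  } else colMeans(ij)
  prof <- intensityProfile(img, mask, id)
  v <- prof$values
  mirrored <- config@tailDirection == "-x"
  if (mirrored) v <- rev(v)
  rec <- data.frame(id = id,
                    row_min = bbox[1], col_min = bbox[2],
                    row_max = bbox[3], col_max = bbox[4],
                    centroid_row = centroid[1], centroid_col = centroid[2],
                    cph = NA_real_, head_radius = NA_real_,
                    tail_length = NA_real_, tail_distance = NA_real_,
                    dna = sum(v), tdna = NA_real_,
                    extent_moment = NA_real_, olive_moment = NA_real_,
                    inertia_moment = NA_real_,
                    box_ratio = width / height, area = area,
                    class_label = "unclassified", flag = "",
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    cph <- findCPH(v)
    r <- headRadius(v, cph, config@headThreshold)
    tb <- tailBounds(v, cph, r)
    da <- dnaAmounts(v, tb$tailCols)
    cd <- cmtAndDistance(v, tb$tailCols, cph)
    mo <- tailMoments(da$tdna, tb$tailLength, cd$tailDistance)
    inertia <- momentOfInertia(v, tb$tailCols, cph, da$dna)
    # cph back to absolute column in the unmirrored frame
    cphAbs <- if (mirrored) prof$colOrigin + (length(v) - cph) else
      prof$colOrigin + cph - 1L
    rec$cph <- cphAbs
    rec$head_radius <- r
    rec$tail_length <- tb$tailLength
    rec$tail_distance <- cd$tailDistance
    rec$dna <- da$dna
    rec$tdna <- da$tdna
    rec$extent_moment <- mo$extent
    rec$olive_moment <- mo$olive
    rec$inertia_moment <- inertia
    flags <- character(0)
    if (cd$flagged) flags <- c(flags, "empty-tail")
    if (!is.na(cd$tailDistance) && cd$tailDistance < 0)
      flags <- c(flags, "negative-tail-distance")
    rec$flag <- paste(flags, collapse = ";")
    rec
  }, cometDegenerate = function(e) {
    rec$flag <- "degenerate"
    rec
  })
  res
}
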