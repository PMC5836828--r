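# Stage 2: gray-level histogram, first-valley / Otsu thresholding and
# connected-component labeling.
#
# Histogram bins are uniform over [0, 256): with the default 256 bins, bin
# b (1-based) holds intensities in [b-1, b), so its left edge equals the
# integer gray level b-1 and a returned threshold t classifies pixels with
# intensity strictly greater than t as foreground.

#' Gray-level histogram of an image
#'
#' @param img numeric matrix, intensities in \code{[0, 255]} (fractional
#'   values allowed).
#' @param bins number of uniform bins over \code{[0, 256)}; default 256.
#' @return object of class \code{"GrayHistogram"}: a list with
#'   \code{counts} (integer, sums to the pixel count), \code{breaks}
#'   (bin edges) and \code{left} (left edge of each bin).
#' @examples
#' h <- grayHistogram(matrix(c(0, 0, 255, 255), 2, 2))
#' h$counts[c(1, 256)]
#' @export
grayHistogram <- function(img, bins = 256L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("bins must be >= 2")
  v <- as.vector(img)
  if (any(v < 0 | v > 255)) stop("intensities must lie in [0, 255]")
  idx <- pmin(bins, floor(v * bins / 256) + 1L)
  counts <- tabulate(idx, nbins = bins)
  structure(list(counts = counts,
                 breaks = seq(0, 256, length.out = bins + 1L),
                 left = (seq_len(bins) - 1) * 256 / bins),
            class = "GrayHistogram")
}

# moving-average smoothing of counts with replicate padding
.smoothCounts <- function(counts, window) {
  if (window <= 1L) return(as.numeric(counts))
  k <- window %/% 2L
  x <- c(rep(counts[1], k), counts, rep(counts[length(counts)], k))
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))[
    (k + 1):(k + length(counts))]
}

# run-length compression: values and leftmost index of each run
.runs <- function(x) {
  r <- rle(x)
  list(values = r$values,
       starts = cumsum(c(1L, r$lengths[-length(r$lengths)])))
}

#' First-valley threshold of a gray-level histogram
#'
#' Comet-assay histograms always have their first peak at the background
#' intensity; the first valley after it separates background from comet
#' pixels at a lower level than Otsu's threshold, preserving faint comets.
#' The histogram counts are moving-average smoothed, the first local
#' maximum is located, and the threshold is the first strict local minimum
#' after it (leftmost index on plateaus).
#'
#' @param hist a \code{"GrayHistogram"}.
#' @param smoothWindow odd moving-average window on the counts; default 5.
#' @return the threshold intensity (left edge of the valley bin), with
#'   attribute \code{"bin"} giving the 1-based bin index. Signals an error
#'   of class \code{"cometNoValley"} when the smoothed histogram has no
#'   valley (monotone or unimodal), in which case callers fall back to
#'   [otsuThreshold()].
#' @examples
#' img <- matrix(c(rep(10, 30), rep(200, 10)), 5, 8)
#' t <- firstValleyThreshold(grayHistogram(img), smoothWindow = 1)
#' @export
firstValleyThreshold <- function(hist, smoothWindow = 5L) {
  stopifnot(inherits(hist, "GrayHistogram"))
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stop("smoothWindow must be an odd positive integer")
  s <- .smoothCounts(hist$counts, smoothWindow)
  r <- .runs(s)
  nv <- length(r$values)
  noValley <- function() stop(structure(
    class = c("cometNoValley", "error", "condition"),
    list(message = "histogram has no valley after its first peak",
         call = sys.call(-1))))
  # first local maximum: first run higher than the following run
  peak <- NA_integer_
  for (i in seq_len(nv - 1L)) {
    if (r$values[i] > r$values[i + 1L]) { peak <- i; break }
  }
  if (is.na(peak)) noValley()
  # first strict local minimum after the peak
  for (i in seq(peak + 1L, length.out = max(0L, nv - peak - 1L))) {
    if (r$values[i] < r$values[i - 1L] && r$values[i] < r$values[i + 1L]) {
      bin <- r$starts[i]
      t <- hist$left[bin]
      attr(t, "bin") <- bin
      return(t)
    }
  }
  noValley()
}

#' Otsu's threshold from a gray-level histogram
#'
#' Exhaustively maximizes the between-class variance
#' \eqn{\sigma^2_B = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all split
#' points; ties are broken toward the smallest threshold. Used as the
#' fallback when the histogram has no valley, and as the comparison
#' baseline for the first-valley rule.
#'
#' @param hist a \code{"GrayHistogram"}.
#' @return the threshold intensity (left edge of the last background bin),
#'   with attribute \code{"bin"}; background is \code{<= t}, foreground
#'   \code{> t}. Signals an error of class \code{"cometDegenerate"} for a
#'   single-valued histogram.
#' @examples
#' img <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
#' otsuThreshold(grayHistogram(img))  # 10
#' @export
otsuThreshold <- function(hist) {
  stopifnot(inherits(hist, "GrayHistogram"))
  cnt <- as.numeric(hist$counts)
  nz <- which(cnt > 0)
  if (length(nz) < 2L) stop(structure(
    class = c("cometDegenerate", "error", "condition"),
    list(message = "histogram is single-valued; no threshold exists",
         call = sys.call())))
  n <- sum(cnt)
  mids <- hist$left
  w0 <- cumsum(cnt) / n                 # mass of class {<= bin k}
  m0 <- cumsum(cnt * mids)
  mu <- m0[length(m0)] / n
  k <- seq_len(length(cnt) - 1L)
  mu0 <- ifelse(w0[k] > 0, m0[k] / (n * w0[k]), 0)
  w1 <- 1 - w0[k]
  mu1 <- ifelse(w1 > 0, (mu - w0[k] * mu0) / w1, 0)
  sb <- w0[k] * w1 * (mu0 - mu1)^2
  best <- which.max(sb)                 # which.max takes the first maximum
  t <- hist$left[best]
  attr(t, "bin") <- best
  t
}

#' Binarize an image at a threshold
#'
#' @param img numeric matrix.
#' @param t threshold intensity; pixels strictly greater than \code{t}
#'   become foreground.
#' @return integer matrix of 0/1.
#' @export
applyThreshold <- function(img, t) {
  matrix(as.integer(img > as.numeric(t)), nrow(img), ncol(img))
}

# neighbor offsets for 4- and 8-connectivity
.connOffsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
}

# raster index (row-major: row 1 left-to-right, then row 2, ...) used for
# deterministic label ordering
.rasterIndex <- function(ij, ncols) (ij[, 1] - 1L) * ncols + ij[, 2]

#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity receive labels
#' 1..n, ordered by each component's first pixel in raster order (row by
#' row, left to right), which makes the labeling deterministic.
#'
#' @param binary integer/logical matrix; nonzero is foreground.
#' @param connectivity 4 or 8 (default 8, the convention used for comet
#'   candidates).
#' @return integer label matrix.
#' @examples
#' m <- matrix(0, 2, 2); m[1, 1] <- m[2, 2] <- 1
#' max(labelComponents(m, 8))  # 1: diagonal pixels connect
#' max(labelComponents(m, 4))  # 2
#' @export
labelComponents <- function(binary, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  dims <- dim(binary)
  fg <- which(binary != 0)
  out <- matrix(0L, dims[1], dims[2])
  if (!length(fg)) return(out)
  rank <- integer(prod(dims)); rank[fg] <- seq_along(fg)
  ij <- arrayInd(fg, dims)
  off <- .connOffsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    nr <- ij[, 1] + off[k, 1]; ncc <- ij[, 2] + off[k, 2]
    ok <- nr >= 1L & nr <= dims[1] & ncc >= 1L & ncc <= dims[2]
    nidx <- (ncc[ok] - 1L) * dims[1] + nr[ok]
    hit <- rank[nidx] > 0L
    from <- c(from, rank[fg[ok]][hit])
    to <- c(to, rank[nidx][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership[seq_along(fg)]
  # relabel by raster order of each component's first pixel
  rast <- .rasterIndex(ij, dims[2])
  firstRast <- tapply(rast, memb, min)
  newLab <- integer(length(firstRast))
  newLab[order(firstRast)] <- seq_along(firstRast)
  out[fg] <- newLab[memb]
  out
}

#' Choose the binarization threshold for an image
#'
#' Applies the configured rule: the first-valley threshold with an
#' automatic Otsu fallback when no valley exists, or Otsu directly.
#'
#' @param img numeric matrix (typically already smoothed).
#' @param config a [CometConfig-class].
#' @return threshold intensity with attribute \code{"method"} recording
#'   which rule produced it.
#' @export
chooseThreshold <- function(img, config = cometConfig()) {
  h <- grayHistogram(img, config@histogramBins)
  if (config@thresholdMethod == "otsu") {
    t <- otsuThreshold(h)
    attr(t, "method") <- "otsu"
    return(t)
  }
  t <- tryCatch(firstValleyThreshold(h, config@histogramSmoothWindow),
                cometNoValley = function(e) NULL)
  if (is.null(t)) {
    t <- otsuThreshold(h)
    attr(t, "method") <- "otsu-fallback"
  } else {
    attr(t, "method") <- "valley"
  }
  t
}
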