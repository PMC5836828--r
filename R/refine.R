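# Stage 3: candidate filtering and overlap correction.
#
# Overlapping comets are separated by turning each candidate mask into a
# topographic relief (Euclidean distance to the nearest background pixel),
# flattening shallow pits with a Haar wavelet approximation, flooding the
# relief from its regional maxima (watershed), re-merging vertically
# stacked chunks that share a column span, and validating each chunk by
# Fourier contour roundness and relative area.

# relabel nonzero labels 1..n by raster order of first pixel
.relabelRaster <- function(labels) {
  fg <- which(labels != 0)
  if (!length(fg)) return(matrix(0L, nrow(labels), ncol(labels)))
  ij <- arrayInd(fg, dim(labels))
  rast <- .rasterIndex(ij, ncol(labels))
  lab <- labels[fg]
  firstRast <- tapply(rast, lab, min)
  newLab <- integer(length(firstRast))
  newLab[order(firstRast)] <- seq_along(firstRast)
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[fg] <- newLab[match(lab, as.integer(names(firstRast)))]
  out
}

#' Remove components touching the image border
#'
#' Comets lying on the boundary of the field of view are mostly truncated
#' and have invalid shapes, so every component with at least one pixel on
#' the first/last row or column is deleted. Remaining components are
#' relabeled 1..n in raster order.
#'
#' @param labels integer label matrix.
#' @return integer label matrix.
#' @export
removeBorderObjects <- function(labels) {
  n <- nrow(labels); m <- ncol(labels)
  border <- unique(c(labels[1, ], labels[n, ], labels[, 1], labels[, m]))
  border <- border[border != 0]
  if (length(border)) labels[labels %in% border] <- 0L
  .relabelRaster(labels)
}

#' Merge small fragments into the closest large component
#'
#' Components with strictly fewer pixels than
#' \code{minFraction * length(labels)} are not deleted outright: debris
#' and detached DNA fragments influence the shape of faint comet types, so
#' each small fragment is relabeled to the nearest large component
#' (minimum Euclidean pixel-to-pixel distance; ties favor the larger
#' component, then the smaller label). When no large component exists the
#' fragments are deleted.
#'
#' @param labels integer label matrix.
#' @param minFraction fraction of total image pixels below which a
#'   component counts as a fragment; default 0.001 (0.1\%).
#' @return integer label matrix, relabeled 1..n in raster order.
#' @export
mergeSmallFragments <- function(labels, minFraction = 0.001) {
  if (!(minFraction > 0 && minFraction < 1))
    stop("minFraction must lie in (0, 1)")
  nTot <- length(labels)
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!length(labs)) return(.relabelRaster(labels))
  area <- vapply(labs, function(l) sum(labels == l), integer(1))
  small <- labs[area < minFraction * nTot]
  large <- labs[area >= minFraction * nTot]
  if (!length(small)) return(.relabelRaster(labels))
  if (!length(large)) {
    labels[labels %in% small] <- 0L
    return(.relabelRaster(labels))
  }
  largePix <- lapply(large, function(l) which(labels == l, arr.ind = TRUE))
  largeArea <- area[match(large, labs)]
  for (s in small) {
    sp <- which(labels == s, arr.ind = TRUE)
    best <- NA_integer_; bestD <- Inf
    for (k in seq_along(large)) {
      lp <- largePix[[k]]
      d2 <- min(outer(sp[, 1], lp[, 1], "-")^2 + outer(sp[, 2], lp[, 2], "-")^2)
      better <- d2 < bestD - 1e-9 ||
        (abs(d2 - bestD) <= 1e-9 && !is.na(best) &&
           (largeArea[k] > largeArea[best] ||
              (largeArea[k] == largeArea[best] && large[k] < large[best])))
      if (is.na(best) || better) { best <- k; bestD <- min(bestD, d2) }
    }
    labels[labels == s] <- large[best]
  }
  .relabelRaster(labels)
}

#' Euclidean distance transform of a binary mask
#'
#' Each foreground pixel is assigned its Euclidean distance to the nearest
#' background pixel, producing the topographic relief the watershed runs
#' on; background pixels get 0. Pixels on the image border treat the
#' outside as background at distance 1 (the mask is padded with a one-pixel
#' background ring before the transform).
#'
#' @param binary integer/logical matrix; nonzero is foreground.
#' @return numeric matrix of distances, zero exactly on background.
#' @export
distanceTransform <- function(binary) {
  n <- nrow(binary); m <- ncol(binary)
  p <- matrix(0, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- as.numeric(binary != 0)
  d <- EBImage::distmap(p, metric = "euclidean")
  matrix(as.numeric(d[2:(n + 1L), 2:(m + 1L)]), n, m)
}

# one level of the 1-D Haar analysis/synthesis with zeroed details:
# columns of x are transformed; length must be even
.haarApproxCols <- function(x) {
  odd <- x[seq(1, nrow(x), by = 2), , drop = FALSE]
  even <- x[seq(2, nrow(x), by = 2), , drop = FALSE]
  (odd + even) / 2  # analysis (a = (o+e)/sqrt2) then synthesis (a/sqrt2)
  # composed: both samples of the pair reconstruct to the pair mean
}

.haarExpandCols <- function(a, n) {
  # reconstruct to 2*nrow(a) samples, then crop to the target length n
  out <- matrix(0, 2L * nrow(a), ncol(a))
  out[seq(1, nrow(out), by = 2), ] <- a
  out[seq(2, nrow(out), by = 2), ] <- a
  out[seq_len(n), , drop = FALSE]
}

#' Haar wavelet smoothing of a relief
#'
#' Performs a multi-level 2-D discrete Haar wavelet decomposition, zeroes
#' all detail coefficients up to the requested level and reconstructs.
#' Shallow pits and spurious maxima narrower than the smoothing scale
#' (\code{2^level} pixels) are flattened, which suppresses
#' over-segmentation in the subsequent watershed. Odd dimensions are
#' replicate-padded and cropped back, and the output is clipped to be
#' non-negative.
#'
#' @param relief numeric matrix of non-negative heights.
#' @param level decomposition depth, >= 1; level 1 equals replacing every
#'   non-overlapping 2x2 block by its mean.
#' @return numeric matrix of the input shape.
#' @export
waveletSmooth <- function(relief, level = 2L) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be a positive integer")
  if (2^level > max(dim(relief)))
    stop("wavelet level ", level, " too large for a ",
         nrow(relief), "x", ncol(relief), " relief")
  n0 <- nrow(relief); m0 <- ncol(relief)
  x <- relief
  dims <- vector("list", level)
  for (l in seq_len(level)) {
    if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
    if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
    dims[[l]] <- dim(x)
    x <- .haarApproxCols(x)
    x <- t(.haarApproxCols(t(x)))
  }
  for (l in rev(seq_len(level))) {
    x <- t(.haarExpandCols(t(x), dims[[l]][2]))
    x <- .haarExpandCols(x, dims[[l]][1])
    x <- x[seq_len(min(nrow(x), if (l > 1) dims[[l - 1]][1] else n0)),
           seq_len(min(ncol(x), if (l > 1) dims[[l - 1]][2] else m0)),
           drop = FALSE]
  }
  pmax(x[seq_len(n0), seq_len(m0), drop = FALSE], 0)
}

# 8-neighbor linear indices for a set of pixels; returns an n x 8 matrix of
# linear indices into the (nr x nc) grid, NA outside
.neighborIndex <- function(pix, nr, nc) {
  ij <- arrayInd(pix, c(nr, nc))
  off <- .connOffsets(8L)
  out <- matrix(NA_integer_, length(pix), 8L)
  for (k in 1:8) {
    r <- ij[, 1] + off[k, 1]; cc <- ij[, 2] + off[k, 2]
    ok <- r >= 1L & r <= nr & cc >= 1L & cc <= nc
    out[ok, k] <- (cc[ok] - 1L) * nr + r[ok]
  }
  out
}

#' Regional maxima of a relief within a mask
#'
#' A regional maximum is a connected plateau of (near-)equal height none
#' of whose 8-neighbors (inside the mask) is higher. Heights within
#' \code{tol} count as equal: distance reliefs are quantized, so ragged
#' mask boundaries produce half-pixel ripples along ridges that would
#' otherwise seed spurious basins. Plateaus are labeled in raster order
#' of their first pixel.
#'
#' @param relief numeric matrix.
#' @param mask integer/logical matrix; only nonzero pixels are considered.
#' @param tol height tolerance for plateau equality; default 0.5 (half a
#'   pixel of distance).
#' @return integer label matrix of seeds (0 elsewhere).
#' @export
regionalMaxima <- function(relief, mask, tol = 0.5) {
  nr <- nrow(relief); nc <- ncol(relief)
  pix <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (!length(pix)) return(out)
  inMask <- matrix(FALSE, nr, nc); inMask[pix] <- TRUE
  nbr <- .neighborIndex(pix, nr, nc)
  h <- relief[pix]
  # plateau adjacency: edges between equal-height mask neighbors
  from <- integer(0); to <- integer(0)
  rank <- integer(nr * nc); rank[pix] <- seq_along(pix)
  hasHigher <- logical(length(pix))
  for (k in 1:8) {
    nb <- nbr[, k]
    valid <- !is.na(nb) & inMask[ifelse(is.na(nb), 1L, nb)]
    nbh <- rep(-Inf, length(pix))
    nbh[valid] <- relief[nb[valid]]
    hasHigher <- hasHigher | (nbh > h + tol)
    eq <- valid & abs(nbh - h) <= tol
    from <- c(from, which(eq)); to <- c(to, rank[nb[eq]])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(pix) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_along(pix)]
  } else {
    memb <- seq_along(pix)
  }
  # a plateau is a maximum iff none of its pixels has a higher neighbor
  bad <- unique(memb[hasHigher])
  isMax <- !(memb %in% bad)
  if (!any(isMax)) return(out)
  ij <- arrayInd(pix, c(nr, nc))
  rast <- .rasterIndex(ij, nc)
  keep <- unique(memb[isMax])
  firstRast <- vapply(keep, function(m) min(rast[memb == m & isMax]),
                      numeric(1))
  lab <- integer(length(keep))
  lab[order(firstRast)] <- seq_along(keep)
  out[pix[isMax]] <- lab[match(memb[isMax], keep)]
  out
}

#' Watershed partition of a component
#'
#' Floods the relief from its regional maxima downwards: pixels are
#' processed level by level in decreasing height; within a level,
#' unassigned pixels repeatedly (simultaneous sweeps) adopt the smallest
#' basin label among their already-assigned 8-neighbors until the level is
#' stable. Every pixel of the parent mask ends up in exactly one basin;
#' the number of basins equals the number of regional maxima. Ties at
#' watershed lines therefore go to the basin with the lowest seed index,
#' making the partition deterministic.
#'
#' @param relief numeric matrix, zero outside \code{parentMask}.
#' @param parentMask integer/logical matrix of the component to split.
#' @param tol plateau tolerance passed to [regionalMaxima()].
#' @return integer label matrix of basins (0 outside the parent).
#' @export
watershedSplit <- function(relief, parentMask, tol = 0.5) {
  nr <- nrow(relief); nc <- ncol(relief)
  pix <- which(parentMask != 0)
  lab <- matrix(0L, nr, nc)
  if (!length(pix)) return(lab)
  seeds <- regionalMaxima(relief, parentMask, tol = tol)
  lab[pix] <- seeds[pix]
  nbr <- .neighborIndex(pix, nr, nc)
  nbr[is.na(nbr)] <- 1L  # dummy; masked below
  inPar <- matrix(FALSE, nr, nc); inPar[pix] <- TRUE
  nbrValid <- matrix(inPar[nbr], nrow(nbr), 8L) &
    !is.na(.neighborIndex(pix, nr, nc))
  h <- relief[pix]
  levels <- sort(unique(h), decreasing = TRUE)
  # repeated descents: a pixel whose level stabilizes before any neighbor
  # is assigned (e.g. a high plateau far from every seed) is revisited on
  # the next descent, so every parent pixel ends up in a basin
  repeat {
    changed <- FALSE
    for (lev in levels) {
      atLev <- which(h == lev & lab[pix] == 0L)
      while (length(atLev)) {
        # simultaneous sweep: all adoptions read the same snapshot
        snap <- lab
        nbLab <- matrix(snap[nbr[atLev, , drop = FALSE]], length(atLev), 8L)
        nbLab[!nbrValid[atLev, , drop = FALSE]] <- 0L
        nbLab[nbLab == 0L] <- NA_integer_
        mins <- suppressWarnings(do.call(pmin, c(lapply(1:8, function(k)
          nbLab[, k]), na.rm = TRUE)))
        gotten <- is.finite(mins)
        if (!any(gotten)) break
        changed <- TRUE
        lab[pix[atLev[gotten]]] <- as.integer(mins[gotten])
        atLev <- atLev[!gotten]
      }
    }
    if (all(lab[pix] > 0L) || !changed) break
  }
  lab
}

#' Merge vertically stacked chunks sharing a column span
#'
#' Watershed over-partitioning of a single comet arises from irregular
#' contours and divides it with near-horizontal cuts; genuinely distinct
#' comets in a chain separate along the electrophoresis (x) direction.
#' Two chunks are therefore merged when they are 8-adjacent, the
#' intersection of their column ranges covers at least \code{overlapMin}
#' of the smaller chunk's column range, and they are actually stacked --
#' their row ranges share at most \code{rowOverlapMax} of the smaller
#' chunk's row range (side-by-side chunks separated by a slanted
#' watershed line are genuine neighbors, not divisions of one shape).
#' The pairwise relation is closed transitively.
#'
#' @param chunks integer label matrix (chunks of one parent component).
#' @param overlapMin minimum column-overlap fraction; default 0.5.
#' @param rowOverlapMax maximum row-overlap fraction for the pair to count
#'   as vertically stacked; default 0.5.
#' @return integer label matrix, relabeled 1..n in raster order.
#' @export
mergeHorizontal <- function(chunks, overlapMin = 0.5, rowOverlapMax = 0.5) {
  labs <- sort(setdiff(unique(as.vector(chunks)), 0L))
  if (length(labs) < 2L) return(.relabelRaster(chunks))
  nr <- nrow(chunks); nc <- ncol(chunks)
  colRange <- lapply(labs, function(l) {
    cc <- which(colSums(chunks == l) > 0)
    c(min(cc), max(cc))
  })
  rowRange <- lapply(labs, function(l) {
    rr <- which(rowSums(chunks == l) > 0)
    c(min(rr), max(rr))
  })
  # adjacency between chunk labels
  pix <- which(chunks != 0)
  nbr <- .neighborIndex(pix, nr, nc)
  own <- chunks[pix]
  adj <- matrix(FALSE, length(labs), length(labs))
  for (k in 1:8) {
    nb <- nbr[, k]
    ok <- !is.na(nb)
    nbl <- chunks[nb[ok]]
    hit <- nbl != 0L & nbl != own[ok]
    if (any(hit)) {
      a <- match(own[ok][hit], labs); b <- match(nbl[hit], labs)
      adj[cbind(a, b)] <- TRUE; adj[cbind(b, a)] <- TRUE
    }
  }
  parent <- seq_along(labs)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i || !adj[i, j]) next
    ri <- colRange[[i]]; rj <- colRange[[j]]
    inter <- min(ri[2], rj[2]) - max(ri[1], rj[1]) + 1L
    smaller <- min(ri[2] - ri[1] + 1L, rj[2] - rj[1] + 1L)
    qi <- rowRange[[i]]; qj <- rowRange[[j]]
    rInter <- min(qi[2], qj[2]) - max(qi[1], qj[1]) + 1L
    rSmaller <- min(qi[2] - qi[1] + 1L, qj[2] - qj[1] + 1L)
    if (inter > 0 && inter / smaller >= overlapMin &&
        rInter / rSmaller <= rowOverlapMax) {
      a <- findRoot(i); b <- findRoot(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(labs), findRoot, integer(1))
  out <- chunks
  out[pix] <- labs[root[match(own, labs)]]
  .relabelRaster(out)
}

#' Fourier shape spectrum of a chunk contour
#'
#' Traces the outer boundary of the chunk (Moore neighborhood), resamples
#' it to \code{nPoints} equally spaced points by arc length, forms the
#' complex sequence col + i*row and applies the discrete Fourier
#' transform. The DC term (pure centroid translation) is discarded; the
#' remaining amplitudes describe shape. For elliptical cells the lowest
#' frequencies dominate: a circle concentrates in the +1 coefficient, an
#' ellipse in the +/-1 pair, and mild asymmetry (a comet's tail taper) in
#' the +/-2 pair.
#'
#' @param chunk integer/logical matrix with a single connected component.
#' @param nPoints contour sample count; default 64.
#' @return object of class \code{"ContourSpectrum"}: list with
#'   \code{amplitudes} (length \code{nPoints - 1}, frequencies 1..n-1 in
#'   FFT order so the +/-1 pair sits at the first and last entries),
#'   \code{nPoints}, and \code{roundness}: the share of the two lowest
#'   frequency magnitudes (the +/-1 and +/-2 pairs) in the total
#'   amplitude.
#' @export
contourSpectrum <- function(chunk, nPoints = 64L) {
  nPoints <- as.integer(nPoints)
  bin <- matrix(as.integer(chunk != 0), nrow(chunk), ncol(chunk))
  if (!any(bin != 0)) stop("empty chunk")
  oc <- EBImage::ocontour(bin)[[1]]
  if (is.null(oc) || nrow(oc) < 4L)
    stop("degenerate chunk: fewer than 4 boundary pixels")
  # ocontour returns 0-based (dim1, dim2) = (row-1, col-1) for our matrices
  rows <- oc[, 1] + 1; cols <- oc[, 2] + 1
  # close the polygon and resample by arc length
  rows <- c(rows, rows[1]); cols <- c(cols, cols[1])
  seg <- sqrt(diff(rows)^2 + diff(cols)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate chunk: zero-length contour")
  si <- seq(0, total, length.out = nPoints + 1L)[seq_len(nPoints)]
  ri <- stats::approx(s, rows, xout = si)$y
  ci <- stats::approx(s, cols, xout = si)$y
  z <- stats::fft(complex(real = ci, imaginary = ri)) / nPoints
  amp <- Mod(z)[-1]
  n <- length(amp)
  low <- amp[1] + amp[n] + if (n >= 3) amp[2] + amp[n - 1] else 0
  structure(list(amplitudes = amp, nPoints = nPoints,
                 roundness = low / sum(amp)),
            class = "ContourSpectrum")
}

#' Validity of a watershed chunk
#'
#' A chunk is a plausible individual cell when (i) the absolute sum of
#' the amplitudes of the two lowest frequencies (the +/-1 and +/-2
#' coefficient pairs, DC excluded) is at least \code{roundnessMin} of the
#' absolute sum over all frequencies, and (ii) its area is at least
#' \code{areaRatioMin} of the initial (parent) mask's area.
#'
#' @param chunk binary matrix of the chunk.
#' @param initialMask binary matrix of the parent mask the chunk came from.
#' @param spectrum optional precomputed [contourSpectrum()] of the chunk.
#' @param roundnessMin default 0.70.
#' @param areaRatioMin default 0.03.
#' @return logical.
#' @export
chunkIsValid <- function(chunk, initialMask, spectrum = NULL,
                         roundnessMin = 0.70, areaRatioMin = 0.03) {
  aInit <- sum(initialMask != 0)
  if (aInit == 0) stop("initial mask is empty")
  aChunk <- sum(chunk != 0)
  if (aChunk / aInit < areaRatioMin) return(FALSE)
  if (is.null(spectrum)) {
    spectrum <- tryCatch(contourSpectrum(chunk), error = function(e) NULL)
    if (is.null(spectrum)) return(FALSE)
  }
  spectrum$roundness >= roundnessMin
}

#' Separate overlapping comets in a label mask
#'
#' For each labeled component: distance transform, Haar wavelet smoothing,
#' watershed from regional maxima, horizontal re-merging, then Fourier/area
#' validity. Invalid chunks are merged into their largest valid 8-adjacent
#' neighbor (preserving DNA totals for characterization) or dropped when no
#' valid neighbor exists. Components whose processing fails (e.g. too small
#' for the wavelet level) are kept unsplit with a warning; the whole image
#' is never aborted.
#'
#' @param labels integer label matrix (after border and fragment
#'   filtering).
#' @param config a [CometConfig-class].
#' @return integer label matrix with former overlaps separated, relabeled
#'   1..n in raster order. Never creates foreground outside the input
#'   foreground.
#' @export
correctOverlaps <- function(labels, config = cometConfig()) {
  labs <- sort(setdiff(unique(as.vector(labels)), 0L))
  out <- matrix(0L, nrow(labels), ncol(labels))
  nextLab <- 0L
  fragPx <- config@smallFragmentFraction * length(labels)
  for (l in labs) {
    sel <- labels == l
    ij <- which(sel, arr.ind = TRUE)
    r0 <- min(ij[, 1]); r1 <- max(ij[, 1])
    c0 <- min(ij[, 2]); c1 <- max(ij[, 2])
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(ij[, 1] - r0 + 1L, ij[, 2] - c0 + 1L)] <- 1L
    # a component can hold disconnected islands only through fragment
    # merging; keep those attached fragments with the main body instead of
    # letting the watershed carve them into free-standing chunks
    islands <- labelComponents(sub, 8L)
    iAreas <- tabulate(islands[islands > 0L])
    attachedIds <- which(iAreas < fragPx & seq_along(iAreas) != which.max(iAreas))
    attached <- islands %in% attachedIds & islands > 0L
    sub[attached] <- 0L
    chunks <- tryCatch({
      relief <- distanceTransform(sub)
      sm <- waveletSmooth(relief, config@waveletLevel)
      sm[sub == 0L] <- 0
      ws <- watershedSplit(sm, sub)
      ws <- .mergeShallowBasins(ws, sm)
      ws <- mergeHorizontal(ws, config@horizontalOverlapMin)
      # validity filtering
      cl <- sort(setdiff(unique(as.vector(ws)), 0L))
      if (length(cl)) {
        valid <- vapply(cl, function(k)
          chunkIsValid(ws == k, sub, roundnessMin = config@roundnessMin,
                       areaRatioMin = config@areaRatioMin), logical(1))
        if (!all(valid)) {
          adjPairs <- .chunkAdjacency(ws, cl)
          sizes <- vapply(cl, function(k) sum(ws == k), integer(1))
          # largest invalid first, so cascades resolve deterministically
          for (k in order(-sizes[!valid])) {
            bad <- cl[!valid][k]
            nbrs <- unique(c(adjPairs[adjPairs[, 1] == bad, 2],
                             adjPairs[adjPairs[, 2] == bad, 1]))
            nbrs <- nbrs[valid[match(nbrs, cl)]]
            if (length(nbrs)) {
              tgt <- nbrs[which.max(sizes[match(nbrs, cl)])]
              ws[ws == bad] <- tgt
            } else {
              ws[ws == bad] <- 0L
            }
          }
        }
      }
      ws
    }, error = function(e) {
      warning("component ", l, " kept unsplit: ", conditionMessage(e),
              call. = FALSE)
      sub
    })
    if (any(attached)) {
      # reattach each merged fragment to its nearest surviving chunk
      cl0 <- sort(setdiff(unique(as.vector(chunks)), 0L))
      if (length(cl0)) {
        chunkPix <- which(chunks != 0, arr.ind = TRUE)
        for (aid in attachedIds) {
          ap <- which(islands == aid, arr.ind = TRUE)
          d2 <- outer(ap[, 1], chunkPix[, 1], "-")^2 +
            outer(ap[, 2], chunkPix[, 2], "-")^2
          nearest <- chunkPix[which.min(apply(d2, 2, min)), , drop = FALSE]
          chunks[ap] <- chunks[nearest]
        }
      }
    }
    cl <- sort(setdiff(unique(as.vector(chunks)), 0L))
    for (k in cl) {
      nextLab <- nextLab + 1L
      idx <- which(chunks == k, arr.ind = TRUE)
      out[cbind(idx[, 1] + r0 - 1L, idx[, 2] + c0 - 1L)] <- nextLab
    }
  }
  .relabelRaster(out)
}

# Merge adjacent watershed basins separated by a shallow saddle: if the
# lower of two basin peaks stands less than hMin above the ridge between
# them, the division is a quantization/noise artifact of the distance
# relief, not a genuine two-cell waist.
.mergeShallowBasins <- function(basins, relief, hMin = 2) {
  labs <- sort(setdiff(unique(as.vector(basins)), 0L))
  if (length(labs) < 2L) return(basins)
  peaks <- vapply(labs, function(l) max(relief[basins == l]), numeric(1))
  pix <- which(basins != 0)
  nbr <- .neighborIndex(pix, nrow(basins), ncol(basins))
  own <- basins[pix]
  hOwn <- relief[pix]
  saddle <- matrix(-Inf, length(labs), length(labs))
  for (k in 1:8) {
    nb <- nbr[, k]
    ok <- !is.na(nb)
    nbl <- basins[nb[ok]]
    hit <- nbl != 0L & nbl != own[ok]
    if (any(hit)) {
      a <- match(own[ok][hit], labs); b <- match(nbl[hit], labs)
      s <- pmin(hOwn[ok][hit], relief[nb[ok][hit]])
      for (m in which(s > saddle[cbind(a, b)])) {
        saddle[a[m], b[m]] <- s[m]
        saddle[b[m], a[m]] <- s[m]
      }
    }
  }
  parent <- seq_along(labs)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i || !is.finite(saddle[i, j])) next
    if (min(peaks[i], peaks[j]) - saddle[i, j] < hMin) {
      a <- findRoot(i); b <- findRoot(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(labs), findRoot, integer(1))
  out <- basins
  out[pix] <- labs[root[match(own, labs)]]
  out
}

# pairs of 8-adjacent chunk labels
.chunkAdjacency <- function(chunks, labs) {
  nr <- nrow(chunks); nc <- ncol(chunks)
  pix <- which(chunks != 0)
  if (!length(pix)) return(matrix(integer(0), 0, 2))
  nbr <- .neighborIndex(pix, nr, nc)
  own <- chunks[pix]
  pairs <- matrix(integer(0), 0, 2)
  for (k in 1:8) {
    nb <- nbr[, k]
    ok <- !is.na(nb)
    nbl <- chunks[nb[ok]]
    hit <- nbl != 0L & nbl != own[ok]
    if (any(hit))
      pairs <- rbind(pairs, cbind(pmin(own[ok][hit], nbl[hit]),
                                  pmax(own[ok][hit], nbl[hit])))
  }
  unique(pairs)
}
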