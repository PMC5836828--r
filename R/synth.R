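# Seeded synthetic comet-assay scenes with full ground truth.
#
# A comet is rendered as an isotropic Gaussian head of peak headPeak
# plus a rightward tail carrying the fraction `damage` of the total
# fluorescent mass: a brightness ramp tapering to an exponential
# roll-off of scale `tailDecay`, with a Gaussian cross-section of width
# ySpread * headSigma. The tail's per-column brightness is capped below
# the head-threshold level so the integrated profile stays unimodal with
# its peak at the head; when the requested mass does not fit under the
# cap, the tail lengthens instead of brightening -- mirroring the physical
# dose response (more damage, longer tail). Rendered intensities below a
# visibility floor (default 6 gray levels, about the background) are
# clipped to zero, giving each comet a finite support whose ground truth
# only contains signal that is in principle distinguishable from
# background in 8-bit data.
#
# Ground-truth records are obtained by applying the same profile
# measurements as the analysis stage to the noiseless render with its
# exact support mask, so pipeline-vs-truth comparisons isolate the effect
# of noise, thresholding and segmentation.

.tailAmpCap <- 0.4  # tail column mass <= this fraction of the head peak column

#' Generative parameters of one synthetic comet
#'
#' Class archetypes: \emph{normal} = bright compact head, minimal tail;
#' \emph{necrosis} = bright head with a long bright tail (tail at least
#' three head sigmas); \emph{apoptosis} = dim head (peak at most 0.4 of
#' the necrosis default of 200) with a diffuse, vertically spread cloud.
#'
#' @param classLabel "normal", "necrosis" or "apoptosis".
#' @param headSigma Gaussian sigma of the head (px).
#' @param headPeak rendered head peak brightness (0--255).
#' @param damage fraction of total mass carried by the tail, in
#'   \code{[0, 0.93]}.
#' @param tailLength nominal tail length (px); may be extended at render
#'   time to carry the requested mass.
#' @param tailDecay exponential roll-off scale of the tail end (px).
#' @param ySpread tail cross-section width as a multiple of
#'   \code{headSigma}.
#' @return object of class \code{"CometSpec"}.
#' @export
cometSpec <- function(classLabel, headSigma, headPeak, damage,
                      tailLength, tailDecay, ySpread = 1) {
  stopifnot(classLabel %in% .cometClasses)
  if (damage < 0 || damage > 0.93)
    stop("damage must lie in [0, 0.93]")
  if (classLabel == "normal" && damage > 0.1)
    stop("normal comets must have damage <= 0.1")
  if (classLabel == "necrosis" && tailLength < 3 * headSigma)
    stop("necrosis comets must have tailLength >= 3 * headSigma")
  if (classLabel == "apoptosis" && headPeak > 80)
    stop("apoptosis comets must have headPeak <= 80 (0.4 x necrosis default)")
  structure(list(classLabel = classLabel, headSigma = headSigma,
                 headPeak = headPeak, damage = damage,
                 tailLength = tailLength, tailDecay = tailDecay,
                 ySpread = ySpread),
            class = "CometSpec")
}

#' Draw a random comet spec of a given class
#'
#' Uses the current RNG state; see the vignette for the archetype ranges.
#'
#' @param classLabel "normal", "necrosis" or "apoptosis".
#' @return a \code{"CometSpec"}.
#' @export
sampleCometSpec <- function(classLabel = .cometClasses) {
  classLabel <- match.arg(classLabel)
  u <- function(a, b) stats::runif(1, a, b)
  switch(classLabel,
    normal = cometSpec("normal", headSigma = u(4.5, 5.5),
                       headPeak = u(160, 220), damage = u(0.01, 0.08),
                       tailLength = u(10, 18), tailDecay = u(2, 4)),
    necrosis = {
      s <- u(4, 5.5)
      cometSpec("necrosis", headSigma = s, headPeak = u(170, 230),
                damage = u(0.45, 0.62),
                tailLength = max(3 * s, u(40, 60)), tailDecay = u(3, 6))
    },
    apoptosis = cometSpec("apoptosis", headSigma = u(5, 7),
                          headPeak = u(65, 80), damage = u(0.45, 0.6),
                          tailLength = u(25, 40), tailDecay = u(4, 8),
                          ySpread = 1.3))
}

# tail amplitude shape: linear ramp from 1 down to 0.4 over the nominal
# length, then an exponential roll-off of scale tau. Strictly decreasing,
# so the detected tail narrows monotonically along x -- a tapering ribbon
# whose distance relief has no spurious ridge maxima.
.tailShape <- function(L, tau) {
  if (L < 1) return(numeric(0))
  n <- L + ceiling(3 * tau)
  dx <- seq_len(n)
  ifelse(dx <= L, 1 - 0.6 * dx / L, 0.4 * exp(-(dx - L) / tau))
}

#' Render one synthetic comet
#'
#' @param spec a \code{"CometSpec"}.
#' @param seed integer seed for the signal-dependent (Poisson-like) noise.
#' @param config a [CometConfig-class]; its head threshold defines the
#'   head/tail split used for the ground-truth record.
#' @param noise logical; add multiplicative shot noise to the returned
#'   patch (the truth is always computed from the noiseless render).
#' @param supportFloor visibility floor (gray levels); rendered intensity
#'   below it is clipped to zero and excluded from the truth support.
#' @return list with \code{patch} (noisy render, no background),
#'   \code{noiseless}, \code{supportMask} (0/1 matrix), \code{truth}
#'   (one-row record data.frame), \code{headPos} (row, col of the head
#'   center) and \code{tailLengthEff} (the rendered tail length).
#' @export
renderComet <- function(spec, seed = 1L, config = cometConfig(),
                        noise = TRUE, supportFloor = 6) {
  stopifnot(inherits(spec, "CometSpec"))
  set.seed(seed)
  s <- spec$headSigma
  sy <- s * spec$ySpread
  d <- spec$damage
  peakEff <- spec$headPeak  # damage moves mass into the tail; class
                            # archetypes encode head dimming
  margin <- ceiling(3.2 * max(s, sy)) + 2L
  r0 <- margin + 1L
  nrows <- 2L * margin + 1L
  rows <- seq_len(nrows)
  cross <- exp(-(rows - r0)^2 / (2 * sy^2))
  headCross <- exp(-(rows - r0)^2 / (2 * s^2))
  # head mass and required tail mass
  leftM <- ceiling(3.2 * s) + 2L
  c0 <- leftM + 1L
  headColShape <- exp(-(seq(-leftM, leftM))^2 / (2 * s^2))
  massHead <- peakEff * sum(headCross) * sum(headColShape)
  L <- max(0L, as.integer(round(spec$tailLength)))
  A <- 0
  tau <- spec$tailDecay
  if (d > 0) {
    sReq <- d / (1 - d) * massHead / sum(cross)
    cap <- .tailAmpCap * peakEff * sum(headCross) / sum(cross)
    unit <- sum(.tailShape(L, tau))
    A <- if (unit > 0) sReq / unit else Inf
    if (A > cap) {
      # lengthen rather than brighten
      L <- as.integer(ceiling((sReq / cap) / 0.7 + tau)) + 1L
      unit <- sum(.tailShape(L, tau))
      A <- sReq / unit
    }
  } else {
    L <- 0L
  }
  nTail <- if (L > 0) length(.tailShape(L, tau)) else 0L
  ncols <- leftM + 1L + nTail + 3L
  cols <- seq_len(ncols)
  head <- peakEff * outer(headCross, exp(-(cols - c0)^2 / (2 * s^2)))
  tail <- matrix(0, nrows, ncols)
  if (L > 0) {
    shape <- .tailShape(L, tau)
    tailCols <- c0 + seq_along(shape)
    keep <- tailCols <= ncols
    tail[, tailCols[keep]] <- A * outer(cross, shape[keep])
  }
  noiseless <- head + tail
  noiseless[noiseless < supportFloor] <- 0
  support <- matrix(as.integer(noiseless > 0), nrows, ncols)
  truth <- characterizeComet(noiseless, support, 1L, config)
  truth$class_label <- spec$classLabel
  patch <- noiseless
  if (noise) {
    jitter <- stats::rnorm(length(patch), 0, 0.3 * sqrt(pmax(patch, 0)))
    patch <- pmax(patch + jitter, 0)
    patch[support == 0] <- 0
  }
  list(patch = patch, noiseless = noiseless, supportMask = support,
       truth = truth, headPos = c(r0, c0), tailLengthEff = L)
}

# dilate a logical mask by `by` pixels (Chebyshev)
.dilate <- function(mask, by) {
  if (by < 1) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(by)) {
    sh <- out
    sh[1:(nr - 1), ] <- sh[1:(nr - 1), ] | out[2:nr, ]
    sh[2:nr, ] <- sh[2:nr, ] | out[1:(nr - 1), ]
    sh[, 1:(nc - 1)] <- sh[, 1:(nc - 1)] | sh[, 2:nc]
    sh[, 2:nc] <- sh[, 2:nc] | sh[, 1:(nc - 1)]
    out <- sh
  }
  out
}

# do two supports touch (overlap or 8-adjacency)?
.touches <- function(a, b) any(.dilate(a, 1) & b)

#' Compose a synthetic comet-assay scene
#'
#' Places comets at seeded random positions, forcing
#' \code{ceiling(overlapRate * nComets)} pairs to touch (offset along the
#' electrophoresis direction, as chained comets occur in real assays),
#' adds small debris speckles and background noise, and returns the image
#' together with complete ground truth.
#'
#' @param nComets number of comets.
#' @param overlapRate fraction in \code{[0, 0.5]}; \code{ceiling(rate *
#'   n)} comet pairs are placed touching.
#' @param nDebris number of debris speckles (each far below the 0.1\%
#'   fragment threshold).
#' @param noiseSd additive Gaussian background noise sd; default 2.
#' @param seed integer seed; the scene is a deterministic function of its
#'   arguments.
#' @param size canvas (rows, cols); default \code{c(416, 608)}. NULL
#'   auto-sizes to fit the comets (useful for single-comet scenes).
#' @param classMix named proportions for normal/necrosis/apoptosis;
#'   default \code{c(0.5, 0.3, 0.2)}.
#' @param specs optional list of \code{"CometSpec"} objects overriding
#'   random sampling; \code{nComets} is then ignored.
#' @param background constant background level; default 8.
#' @param config a [CometConfig-class] (head threshold for truth records).
#' @return a [CometScene-class].
#' @export
composeScene <- function(nComets = 20L, overlapRate = 0.2, nDebris = 8L,
                         noiseSd = 2, seed = 1L, size = c(416L, 608L),
                         classMix = c(normal = 0.5, necrosis = 0.3,
                                      apoptosis = 0.2),
                         specs = NULL, background = 8,
                         config = cometConfig()) {
  set.seed(seed)
  if (is.null(specs)) {
    nComets <- as.integer(nComets)
    counts <- floor(classMix / sum(classMix) * nComets)
    while (sum(counts) < nComets) {
      i <- which.max(classMix / sum(classMix) * nComets - counts)
      counts[i] <- counts[i] + 1L
    }
    classes <- sample(rep(names(classMix), counts))
    specs <- lapply(classes, sampleCometSpec)
  }
  n <- length(specs)
  renders <- lapply(specs, function(sp)
    renderComet(sp, seed = sample.int(2^30, 1), config = config))
  if (is.null(size)) {
    size <- c(max(vapply(renders, function(r) nrow(r$patch), integer(1))) + 30L,
              max(vapply(renders, function(r) ncol(r$patch), integer(1))) + 30L)
  }
  nr <- size[1]; nc <- size[2]
  for (r in renders) {
    if (nrow(r$patch) + 6 > nr || ncol(r$patch) + 6 > nc)
      stop("canvas too small for a rendered comet (",
           nrow(r$patch), "x", ncol(r$patch), " vs ", nr, "x", nc, ")")
  }
  occupied <- matrix(FALSE, nr, nc)  # dilated supports of placed comets
  canvas <- matrix(0, nr, nc)
  bestVal <- matrix(0, nr, nc)
  truthLab <- matrix(0L, nr, nc)
  origin <- matrix(NA_integer_, n, 2)  # top-left placement of each patch

  placeAt <- function(idx, rr, cc) {
    r <- renders[[idx]]
    pr <- nrow(r$patch); pc <- ncol(r$patch)
    rows <- rr:(rr + pr - 1L); cols <- cc:(cc + pc - 1L)
    canvas[rows, cols] <<- canvas[rows, cols] + r$noiseless
    sup <- r$supportMask == 1
    vals <- r$noiseless[sup]
    ij <- which(sup, arr.ind = TRUE)
    gi <- cbind(ij[, 1] + rr - 1L, ij[, 2] + cc - 1L)
    win <- vals > bestVal[gi]
    truthLab[gi[win, , drop = FALSE]] <<- idx
    bestVal[gi] <<- pmax(bestVal[gi], vals)
    occupied[rows, cols] <<- occupied[rows, cols] | .dilate(sup, 3)
    origin[idx, ] <<- c(rr, cc)
  }
  fits <- function(idx, rr, cc, ignoreOcc = NULL) {
    r <- renders[[idx]]
    pr <- nrow(r$patch); pc <- ncol(r$patch)
    if (rr < 4L || cc < 4L || rr + pr - 1L > nr - 3L || cc + pc - 1L > nc - 3L)
      return(FALSE)
    occ <- occupied[rr:(rr + pr - 1L), cc:(cc + pc - 1L)]
    if (!is.null(ignoreOcc)) occ <- occ & !ignoreOcc[rr:(rr + pr - 1L),
                                                     cc:(cc + pc - 1L)]
    !any(occ & (r$supportMask == 1))
  }
  randPos <- function(idx) {
    r <- renders[[idx]]
    c(sample(4:(nr - nrow(r$patch) - 2L), 1),
      sample(4:(nc - ncol(r$patch) - 2L), 1))
  }

  nPairs <- min(ceiling(overlapRate * n), n %/% 2L)
  paired <- if (nPairs > 0) seq_len(2L * nPairs) else integer(0)
  placedOK <- rep(FALSE, n)
  for (p in seq_len(nPairs)) {
    i <- 2L * p - 1L; j <- 2L * p
    done <- FALSE
    for (try in 1:200) {
      pos <- randPos(i)
      if (!fits(i, pos[1], pos[2])) next
      # tentatively place i, then j overlapping i's right end
      ri <- renders[[i]]; rj <- renders[[j]]
      supI <- ri$supportMask == 1
      iRight <- pos[2] + max(which(colSums(supI) > 0)) - 1L
      ov <- sample(2:5, 1)
      ccj <- iRight - ov - (min(which(colSums(rj$supportMask) > 0)) - 1L) + 1L
      drj <- round(stats::runif(1, -0.3, 0.3) *
                     (specs[[i]]$headSigma + specs[[j]]$headSigma))
      rrj <- pos[1] + (ri$headPos[1] - rj$headPos[1]) + drj
      # j may overlap i's support but nothing else
      iGlobal <- matrix(FALSE, nr, nc)
      iGlobal[pos[1]:(pos[1] + nrow(ri$patch) - 1L),
              pos[2]:(pos[2] + ncol(ri$patch) - 1L)] <- .dilate(supI, 3)
      occPlusI <- occupied | iGlobal
      if (rrj < 4L || !fits(j, rrj, ccj, ignoreOcc = iGlobal)) next
      # require the two supports to actually touch
      jGlobal <- matrix(FALSE, nr, nc)
      jGlobal[rrj:(rrj + nrow(rj$patch) - 1L),
              ccj:(ccj + ncol(rj$patch) - 1L)] <- rj$supportMask == 1
      iSupGlobal <- matrix(FALSE, nr, nc)
      iSupGlobal[pos[1]:(pos[1] + nrow(ri$patch) - 1L),
                 pos[2]:(pos[2] + ncol(ri$patch) - 1L)] <- supI
      if (!.touches(iSupGlobal, jGlobal)) next
      placeAt(i, pos[1], pos[2])
      placeAt(j, rrj, ccj)
      placedOK[c(i, j)] <- TRUE
      done <- TRUE
      break
    }
    if (!done) stop("could not place overlapping pair ", p,
                    " after bounded retries")
  }
  for (idx in setdiff(seq_len(n), paired)) {
    done <- FALSE
    for (try in 1:200) {
      pos <- randPos(idx)
      if (fits(idx, pos[1], pos[2])) {
        placeAt(idx, pos[1], pos[2])
        placedOK[idx] <- TRUE
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not place comet ", idx, " after bounded retries")
  }

  # debris speckles, clear of comets so they stay fragments
  debrisOcc <- occupied
  for (k in seq_len(nDebris)) {
    sd_ <- stats::runif(1, 0.8, 1.5)
    pk <- stats::runif(1, 60, 150)
    half <- 4L
    g <- pk * outer(exp(-(-half:half)^2 / (2 * sd_^2)),
                    exp(-(-half:half)^2 / (2 * sd_^2)))
    g[g < 0.5] <- 0
    for (try in 1:100) {
      rr <- sample(6:(nr - 2L * half - 6L), 1)
      cc <- sample(6:(nc - 2L * half - 6L), 1)
      rows <- rr:(rr + 2L * half); cols <- cc:(cc + 2L * half)
      if (any(debrisOcc[rows, cols])) next
      canvas[rows, cols] <- canvas[rows, cols] + g
      debrisOcc[rows, cols] <- TRUE
      break
    }
  }

  sdMap <- sqrt(noiseSd^2 + 0.09 * canvas)
  img <- background + canvas +
    stats::rnorm(length(canvas), 0, 1) * sdMap
  img <- matrix(pmin(pmax(img, 0), 255), nr, nc)

  # truth records shifted to absolute coordinates
  recs <- do.call(rbind, lapply(seq_len(n), function(idx) {
    tr <- renders[[idx]]$truth
    dr <- origin[idx, 1] - 1L; dc <- origin[idx, 2] - 1L
    tr$id <- idx
    tr$row_min <- tr$row_min + dr; tr$row_max <- tr$row_max + dr
    tr$col_min <- tr$col_min + dc; tr$col_max <- tr$col_max + dc
    tr$centroid_row <- tr$centroid_row + dr
    tr$centroid_col <- tr$centroid_col + dc
    tr$cph <- tr$cph + dc
    tr
  }))
  specDf <- do.call(rbind, lapply(seq_len(n), function(idx) {
    sp <- specs[[idx]]
    data.frame(id = idx, class_label = sp$classLabel,
               head_sigma = sp$headSigma, head_peak = sp$headPeak,
               damage = sp$damage, tail_length = renders[[idx]]$tailLengthEff,
               tail_decay = sp$tailDecay, y_spread = sp$ySpread,
               head_row = renders[[idx]]$headPos[1] + origin[idx, 1] - 1L,
               head_col = renders[[idx]]$headPos[2] + origin[idx, 2] - 1L,
               stringsAsFactors = FALSE)
  }))
  new("CometScene", image = img, masks = truthLab,
      centroids = cbind(row = recs$centroid_row, col = recs$centroid_col),
      specs = specDf, records = recs)
}
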