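# Detection metrics: pixel-wise (region-based) and object-wise
# (centroid-based) precision/recall/F1, plus population-level summaries of
# the damage response.

.matchResult <- function(tp, fp, fn, pairs = NULL) {
  pFlag <- tp + fp == 0
  rFlag <- tp + fn == 0
  precision <- if (pFlag) 0 else tp / (tp + fp)
  recall <- if (rFlag) 0 else tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall,
       f1 = f1Score(precision, recall),
       undefined = c(precision = pFlag, recall = rFlag),
       pairs = pairs)
}

#' Region-based (pixel-wise) segmentation metrics
#'
#' Treats the binarization as a binary vector over pixels: a true positive
#' is a comet pixel labeled comet, a false positive a background pixel
#' labeled comet, and so on.
#'
#' @param pred predicted binary/label mask (nonzero = comet).
#' @param truth ground-truth binary/label mask.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{f1} and an \code{undefined} flag vector (zero
#'   denominators are reported as 0 with the flag set, keeping batch
#'   averages computable).
#' @export
regionMetrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape")
  p <- pred != 0; t <- truth != 0
  .matchResult(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Centroid-based detection metrics
#'
#' A predicted comet counts as a true positive when its centroid lies
#' within \code{radius} pixels of an unmatched ground-truth centroid.
#' Matching is one-to-one and maximal: a maximum bipartite matching on
#' the within-radius graph, so no valid pairing is missed even when
#' several comets crowd inside one radius. Among maximum matchings the
#' tie is broken deterministically by preferring closer pairs.
#'
#' @param predCentroids matrix/data.frame with columns (row, col).
#' @param truthCentroids matrix/data.frame with columns (row, col).
#' @param radius match radius in pixels; default 15.
#' @return as [regionMetrics()], plus \code{pairs}: a two-column matrix of
#'   matched (predicted, truth) indices.
#' @export
centroidMatch <- function(predCentroids, truthCentroids, radius = 15) {
  if (radius <= 0) stop("radius must be positive")
  p <- as.matrix(predCentroids); t <- as.matrix(truthCentroids)
  np <- nrow(p); nt <- nrow(t)
  if (np == 0 || nt == 0)
    return(.matchResult(0L, np, nt, pairs = matrix(integer(0), 0, 2)))
  d <- sqrt(outer(p[, 1], t[, 1], "-")^2 + outer(p[, 2], t[, 2], "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  pairs <- matrix(integer(0), 0, 2)
  if (nrow(cand)) {
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, np), rep(TRUE, nt)),
      edges = as.vector(t(cbind(cand[, 1], np + cand[, 2]))))
    # cardinality dominates (large base weight); closer pairs break ties
    base <- (max(d[cand]) + 2) * (np + nt + 1)
    igraph::E(g)$weight <- base - d[cand]
    mm <- igraph::max_bipartite_match(g)$matching
    matched <- which(!is.na(mm[seq_len(np)]))
    pairs <- cbind(matched, as.integer(mm[matched]) - np)
    dimnames(pairs) <- NULL
  }
  tp <- nrow(pairs)
  .matchResult(tp, np - tp, nt - tp, pairs = pairs)
}

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision fraction in \code{[0, 1]}.
#' @param recall fraction in \code{[0, 1]}.
#' @return numeric in \code{[0, 1]}.
#' @examples
#' f1Score(19 / 20, 1)  # 0.974..., prints as 0.97
#' @export
f1Score <- function(precision, recall) {
  if (precision < 0 || precision > 1 || recall < 0 || recall > 1)
    stop("precision and recall must lie in [0, 1]")
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Heterogeneity of the damage response
#'
#' Distribution summary of per-comet tail DNA fractions within one image:
#' genotoxicity assays read not only the mean damage but its spread across
#' cells.
#'
#' @param tdnaValues numeric vector of TDNA fractions (>= 2 values).
#' @param breaks histogram breaks over \code{[0, 1]}; default steps of 0.1.
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{quartiles}
#'   (25/50/75\%), and \code{histogram} (counts per bin).
#' @export
heterogeneitySummary <- function(tdnaValues, breaks = seq(0, 1, by = 0.1)) {
  v <- as.numeric(tdnaValues)
  if (length(v) < 2) stop("need at least 2 TDNA values")
  if (any(v < 0 | v > 1)) stop("TDNA values must lie in [0, 1]")
  h <- hist(v, breaks = breaks, plot = FALSE)
  list(n = length(v), mean = mean(v), sd = stats::sd(v),
       quartiles = stats::quantile(v, c(0.25, 0.5, 0.75)),
       histogram = stats::setNames(h$counts, paste0("[", utils::head(breaks, -1),
                                                    ",", breaks[-1], ")")))
}

#' Equivalent confidence level after discarding comets
#'
#' When a fraction of cells is discarded (e.g. border comets), the same
#' interval width is retained at a lower confidence level. Under the
#' normal-theory reading, a level \code{confFull} interval from
#' \code{nFull} comets has the width of a
#' \eqn{2\Phi(z \sqrt{n_{sub}/n_{full}}) - 1} interval from \code{nSub}
#' comets, with \eqn{z} the \code{confFull} normal quantile. A
#' Student-t variant is provided for small samples.
#'
#' @param nFull original comet count.
#' @param nSub retained comet count (\code{0 < nSub <= nFull}).
#' @param confFull original confidence level in (0, 1).
#' @param method "z" (default) or "t".
#' @return the equivalent confidence level.
#' @examples
#' equivalentConfidence(50, 41, 0.95)
#' @export
equivalentConfidence <- function(nFull, nSub, confFull, method = c("z", "t")) {
  method <- match.arg(method)
  if (!(nSub > 0 && nSub <= nFull)) stop("need 0 < nSub <= nFull")
  if (!(confFull > 0 && confFull < 1)) stop("confFull must lie in (0, 1)")
  a <- (1 + confFull) / 2
  if (method == "z") {
    z <- stats::qnorm(a) * sqrt(nSub / nFull)
    2 * stats::pnorm(z) - 1
  } else {
    q <- stats::qt(a, df = nFull - 1) * sqrt(nSub / nFull)
    2 * stats::pt(q, df = nSub - 1) - 1
  }
}
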