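# Stage 1: noise smoothing. Borders use replicate padding so the output
# keeps the input size, which the downstream labeling requires.

.padReplicate <- function(img, k) {
  if (k == 0L) return(img)
  ri <- c(rep(1L, k), seq_len(nrow(img)), rep(nrow(img), k))
  ci <- c(rep(1L, k), seq_len(ncol(img)), rep(ncol(img), k))
  img[ri, ci, drop = FALSE]
}

#' Smooth an image with a median or moving-average window
#'
#' Every pixel is replaced by the median or the mean of the values inside a
#' centered square window; this blurring reduces noise ahead of
#' thresholding and stabilizes the head/tail dissection. A window of 1 is
#' the identity. Fractional intensities are kept (no re-quantization).
#'
#' @param img numeric matrix on the 0--255 scale.
#' @param method \code{"median"} (default) or \code{"mean"}.
#' @param window odd positive window side in pixels, at most
#'   \code{min(dim(img))}.
#' @return numeric matrix of the same shape; intensities stay within
#'   \code{[min(img), max(img)]}.
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 255
#' smoothImage(m, "median", 3)[2, 2]  # impulse removed
#' @export
smoothImage <- function(img, method = c("median", "mean"), window = 5L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer, got ", window)
  if (window > min(dim(img)))
    stop("window (", window, ") exceeds the smallest image dimension")
  if (window == 1L) return(img)
  k <- window %/% 2L
  p <- .padReplicate(img, k)
  if (method == "median") {
    .medianFilterCpp(p, nrow(img), ncol(img), window)
  } else {
    # box mean via integral image
    s <- rbind(0, apply(p, 2, cumsum))
    s <- cbind(0, t(apply(s, 1, cumsum)))
    n <- nrow(img); m <- ncol(img)
    i1 <- seq_len(n); j1 <- seq_len(m)
    (s[i1 + window, j1 + window, drop = FALSE] -
       s[i1, j1 + window, drop = FALSE] -
       s[i1 + window, j1, drop = FALSE] +
       s[i1, j1, drop = FALSE]) / (window * window)
  }
}
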