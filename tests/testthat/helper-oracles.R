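# Independent brute-force oracles used across the suite. These follow the
# stated definitions directly (exhaustive scans, flood fills, all-pairs
# distances) and share no code with the implementations they check.

# sliding-window smoothing by literal per-pixel window extraction with
# replicate padding
oracleSmooth <- function(img, method, window) {
  k <- window %/% 2
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- c()
    for (di in -k:k) for (dj in -k:k) {
      r <- min(max(i + di, 1), n); cc <- min(max(j + dj, 1), m)
      vals <- c(vals, img[r, cc])
    }
    out[i, j] <- if (method == "median") median(vals) else mean(vals)
  }
  out
}

# per-pixel tally of histogram bins
oracleHistogram <- function(img, bins = 256L) {
  counts <- integer(bins)
  for (v in as.vector(img)) {
    idx <- min(bins, floor(v * bins / 256) + 1)
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# exhaustive between-class variance maximization over all split bins
oracleOtsu <- function(counts, left) {
  n <- sum(counts)
  best <- -Inf; bestBin <- NA
  for (k in seq_len(length(counts) - 1)) {
    w0 <- sum(counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) { sb <- 0 } else {
      mu0 <- sum(counts[1:k] * left[1:k]) / sum(counts[1:k])
      mu1 <- sum(counts[(k + 1):length(counts)] *
                   left[(k + 1):length(counts)]) /
        sum(counts[(k + 1):length(counts)])
      sb <- w0 * w1 * (mu0 - mu1)^2
    }
    if (sb > best + 1e-12) { best <- sb; bestBin <- k }
  }
  bestBin
}

# breadth-first flood fill labeling
oracleLabel <- function(binary, connectivity) {
  n <- nrow(binary); m <- ncol(binary)
  off <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, n, m)
  cur <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (binary[i, j] != 0 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in off) {
          r <- p[1] + o[1]; cc <- p[2] + o[2]
          if (r >= 1 && r <= n && cc >= 1 && cc <= m &&
              binary[r, cc] != 0 && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# all-pairs Euclidean distance transform
oracleDistance <- function(binary) {
  n <- nrow(binary); m <- ncol(binary)
  # outside border counts as background at distance 1: pad
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- binary
  bg <- which(p == 0, arr.ind = TRUE)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (binary[i, j] != 0) {
      out[i, j] <- sqrt(min((bg[, 1] - (i + 1))^2 + (bg[, 2] - (j + 1))^2))
    }
  }
  out
}

# naive regional maxima with plateau tolerance: plateau components by
# repeated scanning, then the higher-neighbor test
oracleRegionalMaxima <- function(relief, mask, tol = 0.5) {
  n <- nrow(relief); m <- ncol(relief)
  plateau <- matrix(0L, n, m)
  cur <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (mask[i, j] != 0 && plateau[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); plateau[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          r <- p[1] + di; cc <- p[2] + dj
          if ((di || dj) && r >= 1 && r <= n && cc >= 1 && cc <= m &&
              mask[r, cc] != 0 && plateau[r, cc] == 0L &&
              abs(relief[r, cc] - relief[p[1], p[2]]) <= tol) {
            plateau[r, cc] <- cur
            queue[[length(queue) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  isMax <- rep(TRUE, cur)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (mask[i, j] != 0) {
      for (di in -1:1) for (dj in -1:1) {
        r <- i + di; cc <- j + dj
        if ((di || dj) && r >= 1 && r <= n && cc >= 1 && cc <= m &&
            mask[r, cc] != 0 && relief[r, cc] > relief[i, j] + tol) {
          isMax[plateau[i, j]] <- FALSE
        }
      }
    }
  }
  # label surviving plateaus in raster order (row-major) of first pixel
  out <- matrix(0L, n, m)
  firstRast <- rep(Inf, cur)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    p <- plateau[i, j]
    if (p > 0 && isMax[p]) {
      firstRast[p] <- min(firstRast[p], (i - 1) * m + j)
    }
  }
  keep <- which(is.finite(firstRast))
  lab <- integer(cur)
  lab[keep[order(firstRast[keep])]] <- seq_along(keep)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    p <- plateau[i, j]
    if (p > 0 && isMax[p]) out[i, j] <- lab[p]
  }
  out
}

# exhaustive flooding by decreasing altitude with simultaneous (snapshot)
# sweeps per level; min-label adoption
oracleWatershed <- function(relief, mask, tol = 0.5) {
  n <- nrow(relief); m <- ncol(relief)
  lab <- oracleRegionalMaxima(relief, mask, tol)
  levels <- sort(unique(relief[mask != 0]), decreasing = TRUE)
  repeat {
    changed <- FALSE
    for (lev in levels) {
      repeat {
        snap <- lab
        any2 <- FALSE
        for (i in seq_len(n)) for (j in seq_len(m)) {
          if (mask[i, j] != 0 && lab[i, j] == 0L && relief[i, j] == lev) {
            nb <- c()
            for (di in -1:1) for (dj in -1:1) {
              r <- i + di; cc <- j + dj
              if ((di || dj) && r >= 1 && r <= n && cc >= 1 && cc <= m &&
                  mask[r, cc] != 0 && snap[r, cc] > 0L) {
                nb <- c(nb, snap[r, cc])
              }
            }
            if (length(nb)) {
              lab[i, j] <- min(nb)
              any2 <- TRUE; changed <- TRUE
            }
          }
        }
        if (!any2) break
      }
    }
    if (all(lab[mask != 0] > 0L) || !changed) break
  }
  lab
}

# exhaustive one-to-one assignment maximizing matches within radius
oracleMaxMatching <- function(pred, truth, radius) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0L)
  d <- sqrt(outer(pred[, 1], truth[, 1], "-")^2 +
              outer(pred[, 2], truth[, 2], "-")^2)
  best <- 0L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  k <- min(np, nt)
  predSets <- combn(np, k, simplify = FALSE)
  truthPerms <- perms(seq_len(nt))
  for (ps in predSets) {
    for (tp in truthPerms) {
      cnt <- sum(d[cbind(ps, tp[seq_len(k)])] <= radius)
      best <- max(best, cnt)
    }
  }
  best
}

# random blob mask used by several fixtures
randomBlobMask <- function(n, m, p = 0.45) {
  matrix(rbinom(n * m, 1, p), n, m)
}
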