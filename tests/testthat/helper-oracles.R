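## Independent oracles used to freeze expected values; intentionally naive
## implementations, kept separate from the package's code paths.

## Population z-scores by direct computation.
oracleZ <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / length(x))
  (x - mu) / sigma
}

## Recursive flood fill counting 8-connected TRUE regions of a matrix.
oracleFloodCount <- function(sig) {
  visited <- matrix(FALSE, nrow(sig), ncol(sig))
  n <- 0L
  for (r in seq_len(nrow(sig))) for (cc in seq_len(ncol(sig))) {
    if (!sig[r, cc] || visited[r, cc]) next
    n <- n + 1L
    stack <- list(c(r, cc))
    visited[r, cc] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; ccc <- p[2] + dc
        if (rr < 1 || ccc < 1 || rr > nrow(sig) || ccc > ncol(sig)) next
        if (sig[rr, ccc] && !visited[rr, ccc]) {
          visited[rr, ccc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, ccc)
        }
      }
    }
  }
  n
}

## Exhaustive 2-means on a vector: tries every split point between sorted
## unique values and returns the assignment minimizing within-cluster SS.
oracle2Means <- function(x) {
  u <- sort(unique(x))
  best <- NULL; bestSS <- Inf
  for (k in seq_len(length(u) - 1)) {
    thr <- (u[k] + u[k + 1]) / 2
    hi <- x > thr
    ss <- sum((x[!hi] - mean(x[!hi]))^2) + sum((x[hi] - mean(x[hi]))^2)
    if (ss < bestSS) { bestSS <- ss; best <- hi }
  }
  best
}

## Minimum pairwise Euclidean distance between two pixel-index sets.
oracleMinDistance <- function(rowsA, colsA, rowsB, colsB) {
  min(sqrt(outer(rowsA, rowsB, "-")^2 + outer(colsA, colsB, "-")^2))
}

## Closed-form OLS R^2.
oracleR2 <- function(y, x) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
}

## A small logical matrix as a mask fixture with a filled rectangle.
maskWithRect <- function(nr, nc, r0, c0, h, w) {
  m <- matrix(FALSE, nr, nc)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

## data.frame of half-open boxes from a matrix (r0, c0, r1, c1 per row).
boxDf <- function(m) {
  m <- matrix(m, ncol = 4, byrow = TRUE)
  data.frame(bbox_r0 = m[, 1], bbox_c0 = m[, 2],
             bbox_r1 = m[, 3], bbox_c1 = m[, 4])
}

## Convenience alias for the internal axis-aligned rectangle polygon.
rectPolygon <- budquant:::rectPolygon

## One standard noiseless scene, generated once per test run.
standardScene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateScene(1024, 1024, nBuds = 10, nMasses = 2,
                              nDebris = 5, nIslets = 2,
                              stainParams = list(noiseSd = 0), seed = 42)
    cache
  }
})
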