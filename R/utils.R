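## Internal helpers shared across modules.

## 8-connected component labeling. EBImage::bwlabel is 4-connected, so
## diagonal-only contacts are merged afterwards with union-find over the
## 4-connected label ids.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  lab <- matrix(as.integer(lab), nrow(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  ## diagonal neighbor pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

## Point-in-polygon with boundary points counted as inside.
## poly: n x 2 matrix (x, y); pts: m x 2 matrix (x, y).
pointsInPolygon <- function(pts, poly) {
  sp::point.in.polygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2]) >= 1
}

## Deterministic substream seeds below 2^31 derived from one master seed.
substreamSeeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Run expr with a local RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

## Half-open 0-based bounding box (r0, c0, r1, c1) from 1-based pixel indices.
bboxFromPixels <- function(rows, cols) {
  c(min(rows) - 1L, min(cols) - 1L, max(rows), max(cols))
}

## Intersection-over-union of two half-open boxes (r0, c0, r1, c1).
boxIoU <- function(a, b) {
  ih <- min(a[3], b[3]) - max(a[1], b[1])
  iw <- min(a[4], b[4]) - max(a[2], b[2])
  if (ih <= 0 || iw <= 0) return(0)
  inter <- ih * iw
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

## Paint a filled disc into a logical matrix; returns the updated matrix.
paintDisc <- function(mask, row, col, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- max(1L, floor(row - radius)); r1 <- min(nr, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(nc, ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  sub <- outer((rr - row)^2, (cc - col)^2, "+") <= radius^2
  mask[rr, cc] <- mask[rr, cc] | sub
  mask
}

## Object measurements from a set of 1-based pixel indices (rows, cols).
## Perimeter is the count of object pixels with at least one 4-neighbor
## outside the object.
measurePixels <- function(rows, cols, dims) {
  nr <- dims[1]
  idx <- (cols - 1L) * nr + rows
  inset <- logical(nr * dims[2])
  inset[idx] <- TRUE
  neighborIn <- function(ok, off) {
    out <- logical(length(idx))
    out[ok] <- inset[idx[ok] + off]
    out
  }
  up    <- neighborIn(rows > 1L, -1L)
  down  <- neighborIn(rows < nr, 1L)
  left  <- neighborIn(cols > 1L, -nr)
  right <- neighborIn(cols < dims[2], nr)
  boundary <- !(up & down & left & right)
  list(area = length(rows),
       perimeter = sum(boundary),
       centroid = c(mean(rows), mean(cols)),
       bbox = bboxFromPixels(rows, cols),
       touches_edge = any(rows == 1L | rows == nr |
                          cols == 1L | cols == dims[2]))
}

## Rectangle polygon helper (x, y order), counter-clockwise, closed implied.
rectPolygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
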