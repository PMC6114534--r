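#' Extract 100 x 100 candidate tiles
#'
#' Crops one 100 x 100 x 3 tile per bud candidate, centered on its centroid;
#' crops that extend past the image border are reflect-padded. Tile order
#' follows the candidate table; each tile carries its candidate id as an
#' attribute.
#'
#' @param image RGB array in 0..255.
#' @param candidates data.frame with `id`, `row`, `col` (e.g. from
#'   [budCandidates()]).
#' @param side tile side in px (default 100).
#' @return list of `side x side x 3` arrays with attribute `id`.
#' @export
extractTiles <- function(image, candidates, side = 100L) {
  d <- dim(image)
  half <- side %/% 2L
  ## reflect-padded index lookup into 1..n
  reflect <- function(i, n) {
    period <- 2L * n
    i <- ((i - 1L) %% period + period) %% period + 1L
    ifelse(i > n, period - i + 1L, i)
  }
  lapply(seq_len(nrow(candidates)), function(k) {
    r0 <- round(candidates$row[k]) - half
    c0 <- round(candidates$col[k]) - half
    rr <- reflect(r0 + seq_len(side) - 1L, d[1])
    cc <- reflect(c0 + seq_len(side) - 1L, d[2])
    tile <- image[rr, cc, , drop = FALSE]
    attr(tile, "id") <- candidates$id[k]
    tile
  })
}

#' Deterministic rule-based bud classifier
#'
#' @param minSolidity minimum solidity (area / convex-hull area) of the
#'   central DAB object (default 0.7).
#' @param maxEccentricity maximum moment eccentricity (default 0.95).
#' @param minDensity minimum mean DAB optical density over the object
#'   (default 0.3).
#' @param areaGate inclusive area gate in px (default the bud gate
#'   300-3125).
#' @return a [RuleBudClassifier-class].
#' @export
ruleBudClassifier <- function(minSolidity = 0.7, maxEccentricity = 0.95,
                              minDensity = 0.3,
                              areaGate = c(BUD_AREA_MIN_PX, BUD_AREA_MAX_PX)) {
  new("RuleBudClassifier", minSolidity = minSolidity,
      maxEccentricity = maxEccentricity, minDensity = minDensity,
      areaGate = areaGate)
}

## Shape features of a pixel set: solidity and moment eccentricity.
shapeFeatures <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(list(solidity = 1, eccentricity = 0))
  pts <- cbind(cols, rows)
  hull <- grDevices::chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  ## shoelace area of the hull through pixel centers, padded by the ~1 px
  ## border the pixels themselves occupy
  hullArea <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  solidity <- if (hullArea > 0) min(n / hullArea, 1) else 1
  mu <- c(mean(cols), mean(rows))
  cxx <- mean((cols - mu[1])^2); cyy <- mean((rows - mu[2])^2)
  cxy <- mean((cols - mu[1]) * (rows - mu[2]))
  tr <- cxx + cyy
  dt <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + dt; l2 <- tr / 2 - dt
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  list(solidity = solidity, eccentricity = ecc)
}

#' @describeIn classifyTiles Deterministic rules on the central DAB object:
#'   the tile is a bud when the 8-connected DAB-positive component at (or
#'   nearest to) the tile center has solidity, eccentricity, mean density
#'   and area inside the configured gates; blank tiles are `not_bud`.
#' @export
setMethod("classifyTiles", "RuleBudClassifier",
  function(model, tiles, threshold = 0.5) {
    res <- lapply(tiles, function(tile) {
      id <- attr(tile, "id")
      sm <- colorDeconvolve(tile)
      fg <- sm@dab > model@minDensity / 2
      fg <- cleanMask(fg, 10, 50)
      p <- 0
      if (any(fg)) {
        lab <- label8(fg)
        ctr <- (dim(tile)[1:2] + 1) / 2
        hit <- lab[round(ctr[1]), round(ctr[2])]
        if (hit == 0L) {
          ## nearest component to the tile center
          idx <- which(lab > 0L)
          rows <- (idx - 1L) %% nrow(lab) + 1L
          cols <- (idx - 1L) %/% nrow(lab) + 1L
          hit <- lab[idx[which.min((rows - ctr[1])^2 + (cols - ctr[2])^2)]]
        }
        idx <- which(lab == hit)
        rows <- (idx - 1L) %% nrow(lab) + 1L
        cols <- (idx - 1L) %/% nrow(lab) + 1L
        sf <- shapeFeatures(rows, cols)
        meanDab <- mean(sm@dab[idx])
        ok <- sf$solidity >= model@minSolidity &&
          sf$eccentricity <= model@maxEccentricity &&
          meanDab > model@minDensity &&
          length(idx) >= model@areaGate[1] && length(idx) <= model@areaGate[2]
        p <- as.numeric(ok)
      }
      data.frame(id = id, p_bud = p,
                 label = if (p >= threshold) "bud" else "not_bud",
                 stringsAsFactors = FALSE)
    })
    if (!length(res))
      return(data.frame(id = integer(), p_bud = numeric(),
                        label = character(), stringsAsFactors = FALSE))
    do.call(rbind, res)
  })

## ---- small convolutional network ------------------------------------------
## Eight computational layers: conv 3x3x16 / ReLU / maxpool 2 /
## conv 3x3x32 / ReLU / maxpool 2 / FC 64 / FC 2 softmax. Implemented with
## im2col + matrix products; deterministic given the seed.

im2col <- function(x, k) {
  ## x: h x w x c -> (h-k+1)(w-k+1) rows x (k*k*c) cols
  d <- dim(x); oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  cols <- matrix(0, oh * ow, k * k * d[3])
  j <- 0L
  for (ch in seq_len(d[3])) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    j <- j + 1L
    cols[, j] <- as.vector(x[dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch])
  }
  cols
}

col2im <- function(cols, dims, k) {
  ## transpose of im2col: scatter-add gradient columns back to image shape
  oh <- dims[1] - k + 1L; ow <- dims[2] - k + 1L
  x <- array(0, dims)
  j <- 0L
  for (ch in seq_len(dims[3])) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    j <- j + 1L
    x[dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch] <-
      x[dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch] + matrix(cols[, j], oh, ow)
  }
  x
}

maxpool2 <- function(x) {
  d <- dim(x); oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  x <- x[seq_len(oh * 2L), seq_len(ow * 2L), , drop = FALSE]
  a <- x[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE]
  b <- x[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE]
  cc <- x[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE]
  dd <- x[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  ## argmax code 1..4 for backprop; ties resolved in fixed order
  arg <- ifelse(a == out, 1L, ifelse(b == out, 2L, ifelse(cc == out, 3L, 4L)))
  list(out = out, arg = arg)
}

maxpool2Back <- function(grad, arg, dims) {
  d <- dims; oh <- dim(grad)[1]; ow <- dim(grad)[2]
  x <- array(0, d)
  for (code in 1:4) {
    sel <- arg == code
    if (!any(sel)) next
    roff <- if (code %in% c(1L, 3L)) 1L else 2L
    coff <- if (code %in% c(1L, 2L)) 1L else 2L
    sub <- x[seq(roff, 2 * oh, 2), seq(coff, 2 * ow, 2), , drop = FALSE]
    sub[sel] <- grad[sel]
    x[seq(roff, 2 * oh, 2), seq(coff, 2 * ow, 2), ] <- sub
  }
  x
}

cnnForward <- function(w, tile) {
  ## center the input: unstained background sits near 245/255
  x <- tile / 255 - 0.86
  c1 <- im2col(x, 3L)                        # 9604 x 27
  z1 <- sweep(c1 %*% w$W1, 2, w$b1, "+")     # 9604 x 16
  a1 <- array(pmax(z1, 0), c(98, 98, 16))
  p1 <- maxpool2(a1)                         # 49 x 49 x 16
  c2 <- im2col(p1$out, 3L)                   # 2209 x 144
  z2 <- sweep(c2 %*% w$W2, 2, w$b2, "+")     # 2209 x 32
  a2 <- array(pmax(z2, 0), c(47, 47, 32))
  p2 <- maxpool2(a2)                         # 23 x 23 x 32
  f <- as.vector(p2$out)                     # 16928
  z3 <- as.vector(f %*% w$W3) + w$b3         # 64
  a3 <- pmax(z3, 0)
  z4 <- as.vector(a3 %*% w$W4) + w$b4        # 2
  z4 <- z4 - max(z4)
  p <- exp(z4) / sum(exp(z4))
  list(x = x, c1 = c1, z1 = z1, p1 = p1, c2 = c2, z2 = z2, p2 = p2,
       f = f, z3 = z3, a3 = a3, p = p)
}

cnnBackward <- function(w, fw, y) {
  ## y: 1 for bud (class index 1), 2 for not_bud; cross-entropy gradient
  dz4 <- fw$p; dz4[y] <- dz4[y] - 1
  g <- list()
  g$W4 <- outer(fw$a3, dz4); g$b4 <- dz4
  da3 <- as.vector(w$W4 %*% dz4)
  dz3 <- da3 * (fw$z3 > 0)
  g$W3 <- outer(fw$f, dz3); g$b3 <- dz3
  df <- as.vector(w$W3 %*% dz3)
  dp2 <- array(df, c(23, 23, 32))
  da2 <- maxpool2Back(dp2, fw$p2$arg, c(47, 47, 32))
  dz2 <- matrix(da2, 47 * 47, 32) * (fw$z2 > 0)
  g$W2 <- crossprod(fw$c2, dz2); g$b2 <- colSums(dz2)
  dc2 <- dz2 %*% t(w$W2)
  dp1 <- col2im(dc2, c(49, 49, 16), 3L)
  da1 <- maxpool2Back(dp1, fw$p1$arg, c(98, 98, 16))
  dz1 <- matrix(da1, 98 * 98, 16) * (fw$z1 > 0)
  g$W1 <- crossprod(fw$c1, dz1); g$b1 <- colSums(dz1)
  g
}

#' Train the small bud-morphology CNN
#'
#' Stochastic gradient descent with momentum on the cross-entropy loss over
#' labeled 100 x 100 x 3 tiles. Training is deterministic given the seed
#' (initialization and shuffling both derive from it). The architecture is
#' two blocks of 3x3 convolution + ReLU + 2x2 max-pooling followed by two
#' fully connected layers with softmax over bud / not bud.
#'
#' @param tiles list of 100 x 100 x 3 arrays.
#' @param labels character vector, "bud" / "not_bud"; both classes must be
#'   present.
#' @param epochs training epochs (desk-scale default 10).
#' @param learningRate SGD learning rate (default 0.005).
#' @param momentum momentum coefficient (default 0.9).
#' @param seed integer seed.
#' @return a [CNNBudClassifier-class] with final training accuracy in
#'   `@meta$accuracy`.
#' @export
trainBudCNN <- function(tiles, labels, epochs = 10, learningRate = 0.005,
                        momentum = 0.9, seed = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("need both classes ('bud' and 'not_bud') in the training labels")
  stopifnot(length(tiles) == length(labels))
  for (t in tiles) stopifnot(identical(dim(t)[1:2], c(100L, 100L)))
  y <- ifelse(labels == "bud", 1L, 2L)
  w <- withSeed(seed, {
    he <- function(nin, nr, nc)
      matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
    list(W1 = he(27, 27, 16), b1 = rep(0, 16),
         W2 = he(144, 144, 32), b2 = rep(0, 32),
         W3 = he(16928, 16928, 64), b3 = rep(0, 64),
         W4 = he(64, 64, 2), b4 = rep(0, 2))
  })
  v <- lapply(w, function(x) x * 0)
  n <- length(tiles)
  order_seeds <- substreamSeeds(seed + 1L, epochs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(order_seeds[ep], sample.int(n))
    for (i in ord) {
      fw <- cnnForward(w, tiles[[i]])
      g <- cnnBackward(w, fw, y[i])
      for (nm in names(w)) {
        v[[nm]] <- momentum * v[[nm]] - learningRate * g[[nm]]
        w[[nm]] <- w[[nm]] + v[[nm]]
      }
    }
  }
  pred <- vapply(tiles, function(t) which.max(cnnForward(w, t)$p), integer(1))
  acc <- mean(pred == y)
  new("CNNBudClassifier", weights = w,
      meta = list(epochs = epochs, learningRate = learningRate,
                  momentum = momentum, seed = seed, accuracy = acc))
}

#' @describeIn classifyTiles Softmax probability of the bud class from the
#'   trained network.
#' @export
setMethod("classifyTiles", "CNNBudClassifier",
  function(model, tiles, threshold = 0.5) {
    res <- lapply(tiles, function(tile) {
      if (!identical(dim(tile)[1:2], c(100L, 100L)))
        stop("CNN tiles must be 100 x 100")
      p <- cnnForward(model@weights, tile)$p[1]
      data.frame(id = attr(tile, "id"), p_bud = p,
                 label = if (p >= threshold) "bud" else "not_bud",
                 stringsAsFactors = FALSE)
    })
    if (!length(res))
      return(data.frame(id = integer(), p_bud = numeric(),
                        label = character(), stringsAsFactors = FALSE))
    do.call(rbind, res)
  })

#' Save / load a trained CNN classifier as portable JSON
#'
#' Weights are serialized as plain JSON so checkpoints are text files.
#'
#' @param model a [CNNBudClassifier-class].
#' @param path file path.
#' @return `loadBudCNN` returns the restored [CNNBudClassifier-class].
#' @export
saveBudCNN <- function(model, path) {
  obj <- list(weights = lapply(model@weights, function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = NULL, data = as.vector(x))),
    meta = model@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveBudCNN
#' @export
loadBudCNN <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- lapply(obj$weights, function(l) {
    d <- suppressWarnings(as.integer(unlist(l$dim)))
    x <- as.numeric(unlist(l$data))
    if (length(d) == 2L && !anyNA(d)) matrix(x, d[1], d[2]) else x
  })
  new("CNNBudClassifier", weights = w, meta = as.list(obj$meta))
}
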