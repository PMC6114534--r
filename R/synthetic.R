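#' Generate a synthetic pan-cytokeratin IHC scene with exact ground truth
#'
#' Renders an IHC-like RGB image through the optical-density forward model
#' of [renderDensities()]: white background, bluish hematoxylin stroma
#' patches, and brown DAB objects of four classes sized around the bud area
#' gate — `mass` and `islet` above 3125 px, `bud` (a compact cluster of 1-5
#' disc-shaped cell profiles of roughly 8-14 um diameter) inside
#' 300-3125 px, `debris` below 300 px. Object supports are recorded as an
#' exact integer truth mask before per-pixel density noise is applied, so
#' ground-truth areas, centroids and bounding boxes are by-construction
#' exact. Objects never overlap and keep a guard gap from each other and
#' from the image edge. Generation is fully seed-deterministic.
#'
#' @param width,height image size in px (>= 512).
#' @param nBuds,nMasses,nDebris,nIslets object counts (>= 0).
#' @param stainParams list overriding any of `dabDensity` (default 0.9),
#'   `stromaHema` (0.2), `objectHema` (0.05), `noiseSd` (0.1, Gaussian
#'   density noise inside brown objects; 0 disables noise).
#' @param pixelAreaUm2 pixel calibration (default 0.24 um2/px, i.e. the
#'   300/3125 px gate corresponds to 72/750 um2).
#' @param seed integer seed.
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(width, height, nBuds = 0, nMasses = 0,
                          nDebris = 0, nIslets = 0, stainParams = list(),
                          pixelAreaUm2 = 0.24, seed = 1) {
  stopifnot(width >= 512, height >= 512,
            nBuds >= 0, nMasses >= 0, nDebris >= 0, nIslets >= 0)
  p <- utils::modifyList(list(dabDensity = 0.9, stromaHema = 0.2,
                              objectHema = 0.05, noiseSd = 0.1),
                         stainParams)
  withSeed(seed, {
    nr <- height; nc <- width
    truthMask <- matrix(0L, nr, nc)
    placed <- data.frame(row = numeric(), col = numeric(), rEff = numeric())
    truth <- list()
    ## microns per pixel edge; cell radii chosen so one cell profile is a
    ## disc of ~8-14 um diameter
    umPerPx <- sqrt(pixelAreaUm2)
    plan <- data.frame(
      label = rep(c("mass", "islet", "bud", "debris"),
                  c(nMasses, nIslets, nBuds, nDebris)),
      stringsAsFactors = FALSE)
    objId <- 0L
    for (k in seq_len(nrow(plan))) {
      lab <- plan$label[k]
      done <- FALSE
      for (try in seq_len(2000L)) {
        geom <- switch(lab,
          mass = {
            r <- stats::runif(1, 80, 110)
            list(centers = cbind(0, 0), radii = r, rEff = r)
          },
          islet = {
            r <- stats::runif(1, 33, 40)
            list(centers = cbind(0, 0), radii = r, rEff = r)
          },
          debris = {
            r <- stats::runif(1, 4, 8)
            list(centers = cbind(0, 0), radii = r, rEff = r)
          },
          bud = {
            nCells <- sample.int(5L, 1L)
            r <- if (nCells == 1L) stats::runif(1, 10.5, 12.5)
                 else stats::runif(1, 8.5, 12)
            ## compact cluster: satellite cells within one radius of the seed
            ang <- stats::runif(nCells, 0, 2 * pi)
            dst <- c(0, stats::runif(max(nCells - 1L, 0), 0.5, 1.0) * r)
            ctr <- cbind(dst * sin(ang), dst * cos(ang))
            list(centers = ctr, radii = rep(r, nCells),
                 rEff = max(dst) + r)
          })
        margin <- geom$rEff + 60
        if (2 * margin >= min(nr, nc))
          stop(sprintf("image too small to place a '%s' object", lab))
        row <- stats::runif(1, margin, nr - margin)
        col <- stats::runif(1, margin, nc - margin)
        if (nrow(placed)) {
          dd <- sqrt((placed$row - row)^2 + (placed$col - col)^2)
          if (any(dd < placed$rEff + geom$rEff + 40)) next
        }
        ## paint the object's support and verify its class-defining area
        sub <- matrix(FALSE, nr, nc)
        for (i in seq_along(geom$radii))
          sub <- paintDisc(sub, row + geom$centers[i, 1],
                           col + geom$centers[i, 2], geom$radii[i])
        area <- sum(sub)
        ok <- switch(lab,
                     bud = area >= 300 && area <= 3125,
                     debris = area < 300,
                     area > 3125)
        if (!ok) next
        objId <- objId + 1L
        truthMask[sub] <- objId
        placed <- rbind(placed,
                        data.frame(row = row, col = col, rEff = geom$rEff))
        idx <- which(sub)
        rows <- (idx - 1L) %% nr + 1L
        cols <- (idx - 1L) %/% nr + 1L
        truth[[objId]] <- data.frame(
          id = objId, label = lab,
          bbox_r0 = min(rows) - 1L, bbox_c0 = min(cols) - 1L,
          bbox_r1 = max(rows), bbox_c1 = max(cols),
          row = mean(rows), col = mean(cols), area_px = area,
          stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
      if (!done)
        stop(sprintf("could not place a '%s' object without overlap", lab))
    }
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(id = integer(), label = character(),
                      bbox_r0 = numeric(), bbox_c0 = numeric(),
                      bbox_r1 = numeric(), bbox_c1 = numeric(),
                      row = numeric(), col = numeric(), area_px = numeric(),
                      stringsAsFactors = FALSE)

    ## stroma: a few large bluish patches under and around everything
    hema <- matrix(0, nr, nc)
    stromaMask <- matrix(FALSE, nr, nc)
    nStroma <- max(2L, round(nr * nc / 350000))
    for (i in seq_len(nStroma)) {
      stromaMask <- paintDisc(stromaMask, stats::runif(1, 0, nr),
                              stats::runif(1, 0, nc),
                              stats::runif(1, min(nr, nc) / 5,
                                           min(nr, nc) / 3))
    }
    hema[stromaMask] <- p$stromaHema
    obj <- truthMask > 0L
    hema[obj] <- hema[obj] + p$objectHema

    dab <- matrix(0, nr, nc)
    dab[obj] <- p$dabDensity
    if (p$noiseSd > 0) {
      nObjPx <- sum(obj)
      noise <- stats::rnorm(nObjPx, 0, p$noiseSd)
      dab[obj] <- pmax(dab[obj] + noise, 0.4 * p$dabDensity)
    }
    img <- renderDensities(hema, dab)
    roi <- rectPolygon(10, 10, nc - 10, nr - 10)
    new("SyntheticScene", image = img, pixelAreaUm2 = pixelAreaUm2,
        truth = truth, truthMask = truthMask, roi = roi,
        seed = as.integer(seed))
  })
}

#' Generate a tile-count field with planted hotspots
#'
#' Background tiles draw from Poisson(`backgroundMean`); every planted
#' hotspot tile draws `floor(backgroundMean) + 1 + Poisson(hotspotShift - 1)`,
#' which is strictly above the background mean and has expectation about
#' `backgroundMean + hotspotShift`.
#'
#' @param rows,cols grid shape.
#' @param backgroundMean mean background count (>= 0).
#' @param hotspotTiles list of integer matrices (n x 2, row then col) giving
#'   the planted hotspot blocks; may be empty.
#' @param hotspotShift positive shift of the hotspot count distribution.
#' @param seed integer seed.
#' @return a [SyntheticCountField-class].
#' @export
generateCountField <- function(rows, cols, backgroundMean,
                               hotspotTiles = list(), hotspotShift = 10,
                               seed = 1) {
  stopifnot(rows >= 1, cols >= 1, backgroundMean >= 0)
  if (length(hotspotTiles) && hotspotShift <= 0)
    stop("hotspotShift must be positive")
  for (h in hotspotTiles) {
    if (any(h[, 1] < 1 | h[, 1] > rows | h[, 2] < 1 | h[, 2] > cols))
      stop("hotspot tile index outside the grid")
  }
  withSeed(seed, {
    counts <- matrix(stats::rpois(rows * cols, backgroundMean), rows, cols)
    for (h in hotspotTiles) {
      n <- nrow(h)
      counts[cbind(h[, 1], h[, 2])] <-
        floor(backgroundMean) + 1L +
        stats::rpois(n, max(hotspotShift - 1, 0))
    }
    new("SyntheticCountField", counts = counts,
        plantedHotspots = hotspotTiles,
        backgroundMean = backgroundMean, hotspotShift = hotspotShift,
        seed = as.integer(seed))
  })
}

#' Generate a paired HE/IHC TMA thumbnail with a known transform
#'
#' Lays out `nCores` circular cores on a jittered grid, renders an HE-like
#' (pinkish cores) and an IHC-like (brownish cores) thumbnail, and places
#' the IHC cores so that the similarity transform mapping IHC (moving)
#' coordinates into the HE (fixed) frame equals the requested parameters.
#' The returned `transform` is therefore exactly what [registerPair()]
#' should recover.
#'
#' @param nCores number of cores (>= 1).
#' @param layout integer(2), grid rows x cols (must hold `nCores`).
#' @param jitter standard deviation of core-center jitter in px.
#' @param rotationDeg,scaleFactor,translation similarity transform (moving
#'   IHC -> fixed HE); translation is (x, y) in px.
#' @param dropMoving integer vector of core indices omitted from the IHC
#'   image (to exercise unmatched-core reporting).
#' @param seed integer seed.
#' @return list with `he` and `ihc` RGB arrays, `transform`
#'   (`scale`, `rotation` in radians, `translation`), `fixedCenters` and
#'   `movingCenters` (x, y per core), and `coreRadius`.
#' @export
generateTmaThumbnailPair <- function(nCores = 12, layout = c(3, 4),
                                     jitter = 2, rotationDeg = 0,
                                     scaleFactor = 1, translation = c(0, 0),
                                     dropMoving = integer(), seed = 1) {
  stopifnot(nCores >= 1, prod(layout) >= nCores)
  withSeed(seed, {
    spacing <- 110; radius <- 38; margin <- 80
    ij <- cbind((seq_len(nCores) - 1L) %/% layout[2],
                (seq_len(nCores) - 1L) %% layout[2])
    cx <- margin + ij[, 2] * spacing + stats::rnorm(nCores, 0, jitter)
    cy <- margin + ij[, 1] * spacing + stats::rnorm(nCores, 0, jitter)
    fixed <- cbind(x = cx, y = cy)
    theta <- rotationDeg * pi / 180
    s <- scaleFactor
    R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
    ## moving -> fixed is p_fix = s R p_mov + t; place moving cores at the
    ## inverse image of the fixed centers
    t0 <- translation
    moving <- t(solve(s * R) %*% (t(fixed) - t0))
    ## shift the moving canvas so all cores fit; fold the shift into t
    shift <- pmax(margin - apply(moving, 2, min), 0)
    if (any(shift > 0)) {
      moving <- sweep(moving, 2, shift, "+")
      t0 <- t0 - as.vector(s * R %*% shift)
    }
    renderCores <- function(centers, radii, coreCol, w, h) {
      img <- array(245, dim = c(h, w, 3))
      for (i in seq_len(nrow(centers))) {
        m <- matrix(FALSE, h, w)
        m <- paintDisc(m, centers[i, 2], centers[i, 1], radii[i])
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[m] <- coreCol[ch]; img[, , ch] <- pl
        }
      }
      img
    }
    radFix <- radius * stats::runif(nCores, 0.95, 1.05)
    wF <- ceiling(max(fixed[, 1]) + margin)
    hF <- ceiling(max(fixed[, 2]) + margin)
    he <- renderCores(fixed, radFix, c(225, 170, 185), wF, hF)
    keep <- setdiff(seq_len(nCores), dropMoving)
    wM <- ceiling(max(moving[keep, 1]) + margin)
    hM <- ceiling(max(moving[keep, 2]) + margin)
    ihc <- renderCores(moving[keep, , drop = FALSE], radFix[keep] / s,
                       c(180, 140, 110), wM, hM)
    list(he = he, ihc = ihc,
         transform = list(scale = s, rotation = theta, translation = t0),
         fixedCenters = fixed,
         movingCenters = moving[keep, , drop = FALSE],
         movingIndex = keep, coreRadius = radius)
  })
}

#' Generate labeled 100 x 100 tiles for classifier training and testing
#'
#' Renders `nBud` tiles each holding one centered synthetic tumor bud and
#' `nOther` non-bud tiles (empty stroma/white background, sub-gate debris,
#' or an elongated DAB streak that violates bud morphology), through the
#' same optical-density model as [generateScene()].
#'
#' @param nBud,nOther tile counts per class.
#' @param noiseSd density noise inside stained objects.
#' @param seed integer seed.
#' @return list with `tiles` (list of 100 x 100 x 3 arrays) and `labels`
#'   (character, "bud" / "not_bud").
#' @export
generateClassifierTiles <- function(nBud, nOther, noiseSd = 0.1, seed = 1) {
  withSeed(seed, {
    makeTile <- function(kind) {
      hema <- matrix(0, 100, 100)
      dab <- matrix(0, 100, 100)
      if (stats::runif(1) < 0.7)
        hema[paintDisc(matrix(FALSE, 100, 100), stats::runif(1, 0, 100),
                       stats::runif(1, 0, 100), 70)] <- 0.2
      sup <- matrix(FALSE, 100, 100)
      if (kind == "bud") {
        nCells <- sample.int(5L, 1L)
        r <- if (nCells == 1L) stats::runif(1, 10.5, 12.5)
             else stats::runif(1, 8.5, 12)
        ang <- stats::runif(nCells, 0, 2 * pi)
        dst <- c(0, stats::runif(max(nCells - 1L, 0), 0.5, 1.0) * r)
        for (i in seq_len(nCells))
          sup <- paintDisc(sup, 50 + dst[i] * sin(ang[i]),
                           50 + dst[i] * cos(ang[i]), r)
      } else if (kind == "debris") {
        sup <- paintDisc(sup, 50, 50, stats::runif(1, 4, 8))
      } else if (kind == "streak") {
        ## elongated DAB streak of bud-gate area but non-bud shape
        ang <- stats::runif(1, 0, pi)
        for (tpos in seq(-38, 38, by = 1.5))
          sup <- paintDisc(sup, 50 + tpos * sin(ang), 50 + tpos * cos(ang),
                           3.5)
      }
      if (any(sup)) {
        dab[sup] <- 0.9
        if (noiseSd > 0)
          dab[sup] <- pmax(dab[sup] + stats::rnorm(sum(sup), 0, noiseSd),
                           0.36)
        hema[sup] <- hema[sup] + 0.05
      }
      renderDensities(hema, dab)
    }
    kinds <- c(rep("bud", nBud),
               sample(c("empty", "debris", "streak"), nOther, replace = TRUE))
    tiles <- lapply(kinds, makeTile)
    for (i in seq_along(tiles)) attr(tiles[[i]], "id") <- i
    list(tiles = tiles,
         labels = ifelse(kinds == "bud", "bud", "not_bud"))
  })
}
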