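#' Detect TMA cores on a thumbnail
#'
#' Cores are darker than the light slide background: the mean-RGB intensity
#' is thresholded with Otsu's method, holes are filled, objects smaller than
#' 25% of the median core area are removed, and the remaining cores are
#' labeled and named row-major (reading order, with rows bucketed by the
#' median core diameter).
#'
#' @param thumbnail RGB array in 0..255.
#' @return a [CoreMap-class]; errors when no core is found.
#' @export
detectCores <- function(thumbnail) {
  gray <- (thumbnail[, , 1] + thumbnail[, , 2] + thumbnail[, , 3]) / 3 / 255
  thr <- EBImage::otsu(EBImage::Image(gray))
  mask <- gray < thr
  if (!any(mask)) stop("no TMA core found on the thumbnail")
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0L) stop("no TMA core found on the thumbnail")
  sz <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sz >= 0.25 * stats::median(sz))
  if (!length(keep)) stop("no TMA core found on the thumbnail")
  idx <- which(lab > 0L & matrix(lab %in% keep, nrow(lab)))
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  cy <- tapply(rows, ids, mean); cx <- tapply(cols, ids, mean)
  area <- tapply(rows, ids, length)
  diam <- 2 * sqrt(area / pi)
  ## row-major naming: bucket rows by the median diameter
  bucket <- round(cy / stats::median(diam))
  ord <- order(bucket, cx)
  cores <- data.frame(id = seq_along(ord),
                      row = as.numeric(cy[ord]), col = as.numeric(cx[ord]),
                      area_px = as.numeric(area[ord]),
                      diameter_px = as.numeric(diam[ord]))
  old <- as.integer(names(cy))[ord]
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- match(ids, old)
  new("CoreMap", cores = cores, labels = out)
}

## Closed-form least-squares similarity fit (Umeyama): maps `from` (n x 2,
## x/y) onto `to`; returns scale s, rotation R (2 x 2) and translation t with
## to ~ s R from + t.
fitSimilarity <- function(from, to) {
  muF <- colMeans(from); muT <- colMeans(to)
  A <- sweep(from, 2, muF); B <- sweep(to, 2, muT)
  S <- crossprod(B, A) / nrow(from)
  sv <- svd(S)
  d <- diag(2)
  if (det(sv$u %*% t(sv$v)) < 0) d[2, 2] <- -1
  R <- sv$u %*% d %*% t(sv$v)
  varF <- mean(rowSums(A^2))
  s <- sum(diag(diag(sv$d) %*% d)) / varF
  t <- muT - as.vector(s * R %*% muF)
  list(scale = s, R = R, rotation = atan2(R[2, 1], R[1, 1]), translation = t)
}

applySimilarity <- function(fit, pts) {
  sweep(pts %*% t(fit$scale * fit$R), 2, fit$translation, "+")
}

#' Register an HE/IHC core-map pair and pair the cores
#'
#' Estimates the similarity transform mapping the moving (IHC) thumbnail
#' coordinates into the fixed (HE) frame from the detected core centroids: an
#' exhaustive 2-point RANSAC-style search over centroid correspondences
#' proposes candidate transforms, the transform with the most inliers wins,
#' and a closed-form least-squares similarity fit over all inlier pairs
#' refines it. When control points are supplied they override the automatic
#' search. Cores are then paired greedily by mapped-centroid distance within
#' an acceptance radius of half the median core diameter.
#'
#' @param fixed,moving [CoreMap-class] objects (from [detectCores()]).
#' @param controlPoints optional data.frame/matrix with columns
#'   `fixed_x`, `fixed_y`, `moving_x`, `moving_y` (>= 2 rows), e.g. read from
#'   CSV; replaces the automatic estimation.
#' @param minInlierFrac minimum fraction of moving cores that must be
#'   inliers for the automatic registration to be accepted (default 0.5).
#' @return a [CorePairing-class]; errors, advising control points, when the
#'   automatic registration does not reach `minInlierFrac`.
#' @export
registerPair <- function(fixed, moving, controlPoints = NULL,
                         minInlierFrac = 0.5) {
  fx <- cbind(fixed@cores$col, fixed@cores$row)
  mv <- cbind(moving@cores$col, moving@cores$row)
  if (!nrow(fx) || !nrow(mv)) stop("both core maps must be non-empty")
  radius <- stats::median(c(fixed@cores$diameter_px,
                            moving@cores$diameter_px)) / 2
  if (!is.null(controlPoints)) {
    cp <- as.data.frame(controlPoints)
    fit <- fitSimilarity(cbind(cp$moving_x, cp$moving_y),
                         cbind(cp$fixed_x, cp$fixed_y))
  } else {
    best <- NULL; bestInl <- -1L
    nF <- nrow(fx); nM <- nrow(mv)
    for (i in seq_len(nM - 1L)) for (j in (i + 1L):nM) {
      dM <- sqrt(sum((mv[i, ] - mv[j, ])^2))
      if (dM < 1e-9) next
      for (a in seq_len(nF)) for (b in seq_len(nF)) {
        if (a == b) next
        dF <- sqrt(sum((fx[a, ] - fx[b, ])^2))
        s <- dF / dM
        if (s < 0.5 || s > 2) next
        fit <- fitSimilarity(mv[c(i, j), ], fx[c(a, b), ])
        mapped <- applySimilarity(fit, mv)
        dmat <- outer(mapped[, 1], fx[, 1], "-")^2 +
                outer(mapped[, 2], fx[, 2], "-")^2
        inl <- sum(apply(dmat, 1, min) <= radius^2)
        if (inl > bestInl) { bestInl <- inl; best <- fit }
      }
    }
    if (is.null(best) || bestInl < minInlierFrac * nM)
      stop("automatic registration failed; supply control points")
    ## refine on all mutually nearest pairs under the best transform
    mapped <- applySimilarity(best, mv)
    dmat <- sqrt(outer(mapped[, 1], fx[, 1], "-")^2 +
                 outer(mapped[, 2], fx[, 2], "-")^2)
    mPair <- apply(dmat, 1, which.min)
    ok <- dmat[cbind(seq_len(nrow(mv)), mPair)] <= radius
    fit <- if (sum(ok) >= 2) fitSimilarity(mv[ok, , drop = FALSE],
                                           fx[mPair[ok], , drop = FALSE])
           else best
  }
  ## greedy one-to-one pairing by ascending mapped distance
  mapped <- applySimilarity(fit, mv)
  dmat <- sqrt(outer(mapped[, 1], fx[, 1], "-")^2 +
               outer(mapped[, 2], fx[, 2], "-")^2)
  cand <- which(dmat <= radius, arr.ind = TRUE)
  pairs <- data.frame(fixed_id = integer(), moving_id = integer(),
                      residual_px = numeric())
  if (nrow(cand)) {
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    usedM <- logical(nrow(mv)); usedF <- logical(nrow(fx))
    for (k in seq_len(nrow(cand))) {
      m <- cand[k, 1]; f <- cand[k, 2]
      if (usedM[m] || usedF[f]) next
      usedM[m] <- TRUE; usedF[f] <- TRUE
      pairs <- rbind(pairs, data.frame(
        fixed_id = fixed@cores$id[f], moving_id = moving@cores$id[m],
        residual_px = dmat[m, f]))
    }
  }
  new("CorePairing", scale = fit$scale, rotation = fit$rotation,
      translation = fit$translation, pairs = pairs,
      unmatchedFixed = setdiff(fixed@cores$id, pairs$fixed_id),
      unmatchedMoving = setdiff(moving@cores$id, pairs$moving_id))
}
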