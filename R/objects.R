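## Size gate for tumor buds: stained area of 72-750 um2, i.e. 300-3125 px
## at 0.24 um2 per pixel.
BUD_AREA_MIN_PX <- 300
BUD_AREA_MAX_PX <- 3125

sizeClass <- function(areaPx) {
  ifelse(areaPx < BUD_AREA_MIN_PX, "debris",
         ifelse(areaPx > BUD_AREA_MAX_PX, "islet_or_mass", "bud_candidate"))
}

## Build an ObjectSet from an arbitrary integer label matrix; ids are
## renumbered 1..n in increasing order of the original ids.
measureLabels <- function(labels, pixelAreaUm2) {
  idx <- which(labels > 0L)
  dims <- dim(labels)
  if (!length(idx)) {
    df <- data.frame(id = integer(), row = numeric(), col = numeric(),
                     area_px = numeric(), area_um2 = numeric(),
                     perimeter_px = numeric(), bbox_r0 = numeric(),
                     bbox_c0 = numeric(), bbox_r1 = numeric(),
                     bbox_c1 = numeric(), size_class = character(),
                     touches_edge = logical(), final_label = character(),
                     stringsAsFactors = FALSE)
    return(new("ObjectSet", objects = df,
               labels = matrix(0L, dims[1], dims[2]),
               pixelAreaUm2 = pixelAreaUm2))
  }
  ids <- labels[idx]
  rows <- (idx - 1L) %% dims[1] + 1L
  cols <- (idx - 1L) %/% dims[1] + 1L
  uid <- sort(unique(ids))
  newId <- match(ids, uid)
  out <- matrix(0L, dims[1], dims[2])
  out[idx] <- newId
  groups <- split(seq_along(idx), newId)
  meas <- lapply(groups, function(g) measurePixels(rows[g], cols[g], dims))
  df <- data.frame(
    id = seq_along(uid),
    row = vapply(meas, function(m) m$centroid[1], numeric(1)),
    col = vapply(meas, function(m) m$centroid[2], numeric(1)),
    area_px = vapply(meas, function(m) m$area, numeric(1)),
    perimeter_px = vapply(meas, function(m) m$perimeter, numeric(1)),
    bbox_r0 = vapply(meas, function(m) m$bbox[1], numeric(1)),
    bbox_c0 = vapply(meas, function(m) m$bbox[2], numeric(1)),
    bbox_r1 = vapply(meas, function(m) m$bbox[3], numeric(1)),
    bbox_c1 = vapply(meas, function(m) m$bbox[4], numeric(1)),
    touches_edge = vapply(meas, function(m) m$touches_edge, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  df$area_um2 <- df$area_px * pixelAreaUm2
  df$size_class <- sizeClass(df$area_px)
  df$final_label <- NA_character_
  df <- df[, c("id", "row", "col", "area_px", "area_um2", "perimeter_px",
               "bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1", "size_class",
               "touches_edge", "final_label")]
  new("ObjectSet", objects = df, labels = out, pixelAreaUm2 = pixelAreaUm2)
}

#' Label and measure connected foreground components
#'
#' Extracts 8-connected components from the binary foreground mask, measures
#' area, perimeter (boundary pixel count), centroid and bounding box, and
#' assigns the size class from the bud area gate: `debris` below 300 px,
#' `bud_candidate` in 300-3125 px, `islet_or_mass` above 3125 px. Objects
#' touching the image edge are flagged and excluded from bud candidacy
#' downstream.
#'
#' @param mask a [ForegroundMask-class] or a logical matrix.
#' @param pixelAreaUm2 pixel area in square microns (default 0.24).
#' @return an [ObjectSet-class]; empty mask gives an empty set.
#' @export
labelComponents <- function(mask, pixelAreaUm2 = 0.24) {
  if (is(mask, "ForegroundMask")) mask <- mask@mask
  stopifnot(is.matrix(mask))
  measureLabels(label8(mask), pixelAreaUm2)
}

#' Merge nearby objects of equal morphology
#'
#' First clustering stage: objects whose centroids are within `distancePx`
#' and whose areas and perimeters agree within a relative tolerance are
#' combined (transitively) into one object and re-measured on the union of
#' their pixels. This recombines large tumor areas that were split by
#' uneven staining.
#'
#' @param objset an [ObjectSet-class].
#' @param distancePx maximum centroid distance (default 50 px).
#' @param relTolerance relative tolerance on area and perimeter
#'   (default 0.2).
#' @return a re-measured [ObjectSet-class].
#' @export
mergeSimilar <- function(objset, distancePx = 50, relTolerance = 0.2) {
  df <- objset@objects
  n <- nrow(df)
  if (n < 2L) return(objset)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((df$row[i] - df$row[j])^2 + (df$col[i] - df$col[j])^2)
    if (d > distancePx) next
    if (abs(df$area_px[i] - df$area_px[j]) /
        max(df$area_px[i], df$area_px[j]) > relTolerance) next
    if (abs(df$perimeter_px[i] - df$perimeter_px[j]) /
        max(df$perimeter_px[i], df$perimeter_px[j]) > relTolerance) next
    ra <- find(i); rb <- find(j)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  if (all(root == seq_len(n))) return(objset)
  labels <- objset@labels
  labels[labels > 0L] <- root[labels[labels > 0L]]
  measureLabels(labels, objset@pixelAreaUm2)
}

#' Absorb small fragments into nearby tumor masses
#'
#' Second clustering stage: any object that is not itself an
#' `islet_or_mass` and whose minimum boundary-to-boundary distance to a mass
#' is at most `borderDistancePx` is merged into that mass (ties between
#' masses are broken toward the nearer, then the larger mass). Passes repeat
#' until stable, so every remaining bud candidate is guaranteed to lie
#' farther than `borderDistancePx` from every mass.
#'
#' @param objset an [ObjectSet-class] (after [mergeSimilar()]).
#' @param borderDistancePx absorption radius in px (default 25,
#'   about one tumor-cell diameter at 0.49 um/px).
#' @return a re-measured [ObjectSet-class].
#' @export
absorbIntoMass <- function(objset, borderDistancePx = 25) {
  repeat {
    df <- objset@objects
    masses <- df$id[df$size_class == "islet_or_mass"]
    small <- df$id[df$size_class != "islet_or_mass"]
    if (!length(masses) || !length(small)) return(objset)
    labels <- objset@labels
    ## distance of every pixel to each mass (Euclidean distance transform)
    distTo <- lapply(masses, function(m) {
      src <- matrix(1, nrow(labels), ncol(labels))
      src[labels == m] <- 0
      as.matrix(EBImage::distmap(src, metric = "euclidean"))
    })
    names(distTo) <- as.character(masses)
    massArea <- df$area_px[match(masses, df$id)]
    changed <- FALSE
    for (s in small) {
      pix <- which(labels == s)
      dmin <- vapply(distTo, function(dm) min(dm[pix]), numeric(1))
      ok <- which(dmin <= borderDistancePx)
      if (!length(ok)) next
      ## nearer mass wins; ties toward the larger mass
      best <- ok[order(dmin[ok], -massArea[ok])][1]
      labels[pix] <- masses[best]
      changed <- TRUE
    }
    if (!changed) return(objset)
    objset <- measureLabels(labels, objset@pixelAreaUm2)
  }
}

#' Delaunay neighborhood graph of object centroids
#'
#' Triangulates the object centroids and reports per-edge Euclidean
#' distances and the nearest-neighbor distance of every object. With fewer
#' than three objects, or a degenerate (e.g. collinear) point set, the
#' complete graph is used instead, with a warning in the degenerate case.
#'
#' @param objset an [ObjectSet-class] with at least one object.
#' @return a [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(objset) {
  df <- objset@objects
  n <- nrow(df)
  if (n < 1L) stop("need at least one object")
  completeGraph <- function() {
    if (n < 2L)
      return(data.frame(from = integer(), to = integer(),
                        distance_px = numeric()))
    pr <- t(utils::combn(n, 2))
    data.frame(from = df$id[pr[, 1]], to = df$id[pr[, 2]],
               distance_px = sqrt((df$row[pr[, 1]] - df$row[pr[, 2]])^2 +
                                  (df$col[pr[, 1]] - df$col[pr[, 2]])^2))
  }
  if (n < 3L) {
    edges <- completeGraph()
    degen <- TRUE
  } else {
    edges <- tryCatch({
      dd <- deldir::deldir(df$col, df$row)
      sg <- dd$delsgs
      data.frame(from = df$id[pmin(sg$ind1, sg$ind2)],
                 to = df$id[pmax(sg$ind1, sg$ind2)],
                 distance_px = sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2))
    }, error = function(e) NULL)
    degen <- is.null(edges)
    if (degen) {
      warning("degenerate centroid set; falling back to the complete graph")
      edges <- completeGraph()
    }
  }
  nn <- rep(NA_real_, n)
  names(nn) <- as.character(df$id)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      f <- as.character(edges$from[k]); t <- as.character(edges$to[k])
      d <- edges$distance_px[k]
      nn[f] <- min(nn[f], d, na.rm = TRUE)
      nn[t] <- min(nn[t], d, na.rm = TRUE)
    }
  }
  new("NeighborGraph", edges = edges, nnDistance = nn, degenerate = degen)
}
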