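#' Lay a virtual-TMA grid over a region of interest
#'
#' Places grid points `spacing` px apart on an axis-aligned lattice anchored
#' at the top-left corner of the ROI bounding box and keeps every point that
#' falls inside the ROI polygon. Each grid point is the center of one square
#' virtual core of side `tileSide` px; with the defaults
#' (spacing 1800, side 3600 = twice the spacing, approximating one TMA core
#' diameter) neighboring cores overlap by 50%. Candidate points span the
#' half-open bounding box `[xmin, xmax) x [ymin, ymax)`; points on the ROI
#' boundary count as inside.
#'
#' @param roi numeric matrix (n x 2, columns x and y) of a simple polygon.
#' @param spacing grid-point distance in px (default 1800).
#' @param tileSide core side in px (default `2 * spacing`).
#' @return a [TileGrid-class]; errors when no grid point falls inside the
#'   ROI.
#' @export
makeGrid <- function(roi, spacing = 1800, tileSide = 2 * spacing) {
  stopifnot(is.matrix(roi), ncol(roi) == 2, nrow(roi) >= 3,
            spacing > 0, tileSide > 0)
  shoelace <- abs(sum(roi[, 1] * c(roi[-1, 2], roi[1, 2]) -
                      c(roi[-1, 1], roi[1, 1]) * roi[, 2])) / 2
  if (shoelace < tileSide^2)
    stop("ROI is smaller than one virtual core; use a smaller spacing/side")
  xr <- range(roi[, 1]); yr <- range(roi[, 2])
  ## half-open candidate lattice [min, max): the last index strictly below
  ## the upper bound (with a relative tolerance against seq()-style fuzz)
  lattice <- function(r) {
    kMax <- floor((r[2] - r[1]) / spacing - 1e-9)
    r[1] + spacing * seq.int(0L, max(kMax, 0L))
  }
  xs <- lattice(xr)
  ys <- lattice(yr)
  cand <- cbind(x = rep(xs, times = length(ys)),
                y = rep(ys, each = length(xs)))
  inside <- pointsInPolygon(cand, roi)
  if (!any(inside))
    stop("no grid point falls inside the ROI; use a smaller spacing")
  keep <- cand[inside, , drop = FALSE]
  tiles <- data.frame(
    row_idx = as.integer(round((keep[, 2] - yr[1]) / spacing)) + 1L,
    col_idx = as.integer(round((keep[, 1] - xr[1]) / spacing)) + 1L,
    center_x = keep[, 1], center_y = keep[, 2],
    n_buds = NA_real_, grade = NA_integer_)
  tiles <- tiles[order(tiles$row_idx, tiles$col_idx), , drop = FALSE]
  rownames(tiles) <- NULL
  new("TileGrid", tiles = tiles, spacing = spacing, tileSide = tileSide,
      roi = roi)
}

#' Count buds per virtual core
#'
#' A bud is counted in every core whose square half-open footprint
#' `[cx - side/2, cx + side/2) x [cy - side/2, cy + side/2)` contains its
#' centroid. Cores overlap by design, so one bud may contribute to several
#' neighboring cores; a bud sitting exactly on a shared footprint edge is
#' counted in the lower-index core only, by the half-open convention.
#'
#' @param grid a [TileGrid-class].
#' @param buds data.frame of bud centroids with `col` and `row` (pixel
#'   coordinates, as from [buds()]) or columns `x` and `y`.
#' @param scheme optional [gradingScheme()] used to grade each core count.
#' @return the grid with `n_buds` (and, given a scheme, `grade`) filled in.
#' @export
countBudsPerTile <- function(grid, buds, scheme = NULL) {
  tiles <- grid@tiles
  half <- grid@tileSide / 2
  if (nrow(buds) == 0) {
    tiles$n_buds <- 0
  } else {
    bx <- if ("x" %in% names(buds)) buds$x else buds$col
    by <- if ("y" %in% names(buds)) buds$y else buds$row
    tiles$n_buds <- vapply(seq_len(nrow(tiles)), function(i) {
      sum(bx >= tiles$center_x[i] - half & bx < tiles$center_x[i] + half &
          by >= tiles$center_y[i] - half & by < tiles$center_y[i] + half)
    }, numeric(1))
  }
  if (!is.null(scheme))
    tiles$grade <- vapply(tiles$n_buds, budGrade, integer(1), scheme = scheme)
  methods::initialize(grid, tiles = tiles)
}
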