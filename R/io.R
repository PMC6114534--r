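#' Read and write RGB raster images
#'
#' Thin wrappers over the PNG and TIFF readers that present every image as a
#' base array `height x width x 3` with values in 0..255; the format follows
#' the file extension.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @param image RGB array in 0..255.
#' @return `readRasterImage` returns the array; `writeRasterImage` the path.
#' @export
readRasterImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname readRasterImage
#' @export
writeRasterImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  x <- image / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG with threshold metadata
#'
#' @param mask a [ForegroundMask-class].
#' @param path PNG path; the k-means cluster centers go to a JSON sidecar
#'   `<path>.json`.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask@mask), nrow(mask@mask)), path)
  jsonlite::write_json(list(centers = mask@centers),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

## bbox (r0, c0, r1, c1), half-open 0-based -> closed GeoJSON rectangle in
## (x, y) = (col, row) coordinates
bboxToRing <- function(b) {
  list(list(c(b[2], b[1]), c(b[4], b[1]), c(b[4], b[3]), c(b[2], b[3]),
            c(b[2], b[1])))
}

#' Write objects or ground truth as GeoJSON
#'
#' Each object becomes a Polygon feature over its bounding box with its
#' measurements as properties; coordinates are (x, y) = (column, row),
#' 0-based half-open.
#'
#' @param df data.frame with bbox columns and any property columns
#'   (e.g. [objTable()] or a scene's `truth`).
#' @param path output path.
#' @export
writeObjectsGeoJSON <- function(df, path) {
  props <- setdiff(names(df), c("bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = bboxToRing(as.numeric(
                           df[i, c("bbox_r0", "bbox_c0", "bbox_r1",
                                   "bbox_c1")]))),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of bounding boxes
#'
#' Inverse of [writeObjectsGeoJSON()]: rebuilds the bbox columns from each
#' Polygon's coordinate range and restores the property columns.
#'
#' @param path GeoJSON path.
#' @return data.frame with `bbox_r0`, `bbox_c0`, `bbox_r1`, `bbox_c1` and
#'   the stored properties.
#' @export
readObjectsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    b <- data.frame(bbox_r0 = min(xy[, 2]), bbox_c0 = min(xy[, 1]),
                    bbox_r1 = max(xy[, 2]), bbox_c1 = max(xy[, 1]))
    cbind(b, as.data.frame(f$properties, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Write and read ROI polygons as GeoJSON
#'
#' @param roi n x 2 matrix (x, y).
#' @param path file path.
#' @export
writeRoiGeoJSON <- function(roi, path) {
  ring <- lapply(seq_len(nrow(roi)), function(i) as.numeric(roi[i, ]))
  ring <- c(ring, ring[1])
  jsonlite::write_json(
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(role = "roi")),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRoiGeoJSON
#' @export
readRoiGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  xy <- do.call(rbind, lapply(gj$geometry$coordinates[[1]], unlist))
  xy[-nrow(xy), , drop = FALSE]
}

#' Write per-tile results as CSV
#'
#' Columns row, col, center_x, center_y, n_buds, grade.
#'
#' @param grid a [TileGrid-class] (after [countBudsPerTile()]).
#' @param path CSV path.
#' @export
writeTilesCSV <- function(grid, path) {
  t <- grid@tiles
  utils::write.csv(data.frame(row = t$row_idx, col = t$col_idx,
                              center_x = t$center_x, center_y = t$center_y,
                              n_buds = t$n_buds, grade = t$grade),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read a synthetic count field as CSV (row, col, count)
#'
#' @param field a [SyntheticCountField-class] or counts matrix.
#' @param path CSV path.
#' @export
writeCountFieldCSV <- function(field, path) {
  m <- if (is(field, "SyntheticCountField")) field@counts else field
  utils::write.csv(data.frame(row = as.vector(row(m)),
                              col = as.vector(col(m)),
                              count = as.vector(m)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountFieldCSV
#' @export
readCountFieldCSV <- function(path) {
  d <- utils::read.csv(path)
  m <- matrix(0, max(d$row), max(d$col))
  m[cbind(d$row, d$col)] <- d$count
  m
}

#' Write a hotspot summary as JSON
#'
#' @param hs a [HotspotResult-class].
#' @param path JSON path.
#' @export
writeHotspotJSON <- function(hs, path) {
  jsonlite::write_json(
    list(n_hotspots = hs@nHotspots,
         n_hotspots_normalized = hs@nHotspotsNormalized,
         threshold = hs@threshold,
         hotspots = hs@summary),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read registration control points from CSV
#'
#' Expected columns: `fixed_x`, `fixed_y`, `moving_x`, `moving_y`.
#'
#' @param path CSV path.
#' @return data.frame usable as `controlPoints` in [registerPair()].
#' @export
readControlPoints <- function(path) {
  cp <- utils::read.csv(path)
  need <- c("fixed_x", "fixed_y", "moving_x", "moving_y")
  if (!all(need %in% names(cp)))
    stop("control point CSV needs columns: ", paste(need, collapse = ", "))
  cp
}
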