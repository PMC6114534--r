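#' @import methods
NULL

## Central containers. Images are plain base-R arrays (rows = y, cols = x,
## third dim = RGB in 0..255) so that every operation is index-transparent;
## EBImage is used for morphology primitives on matrices.

#' SyntheticScene: a rendered IHC-like image with exact ground truth
#'
#' Container produced by [generateScene()]. Holds the 8-bit RGB image, the
#' pixel calibration, a ground-truth table of planted objects (label,
#' bounding box, centroid, area) recorded from the binary support masks
#' before any rendering noise, and the region-of-interest polygon.
#'
#' @slot image numeric array, height x width x 3, values in 0..255.
#' @slot pixelAreaUm2 numeric(1), tissue area of one pixel in square microns.
#' @slot truth data.frame with one row per planted object: `label`
#'   (bud/islet/mass/debris), half-open 0-based bounding box
#'   (`bbox_r0`,`bbox_c0`,`bbox_r1`,`bbox_c1`), centroid (`row`,`col`) and
#'   `area_px`.
#' @slot truthMask integer matrix, planted-object id per pixel (0 background).
#' @slot roi numeric matrix (n x 2, columns x/y) with the border-zone polygon.
#' @slot seed integer(1) used for generation.
#'
#' @export
setClass("SyntheticScene",
  representation(image = "array", pixelAreaUm2 = "numeric",
                 truth = "data.frame", truthMask = "matrix",
                 roi = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
      msg <- c(msg, "image must be a height x width x 3 array")
    if (any(object@image < 0) || any(object@image > 255))
      msg <- c(msg, "image values must lie in [0, 255]")
    if (nrow(object@truth) > 0) {
      a <- object@truth$area_px
      lb <- object@truth$label
      if (any(lb == "bud" & (a < 300 | a > 3125)))
        msg <- c(msg, "truth buds must have area in [300, 3125] px")
      if (any(lb == "debris" & a >= 300))
        msg <- c(msg, "truth debris must have area < 300 px")
      if (any(lb %in% c("islet", "mass") & a <= 3125))
        msg <- c(msg, "truth islets/masses must have area > 3125 px")
    }
    if (length(msg)) msg else TRUE
  })

#' SyntheticCountField: a tile-count lattice with planted hotspots
#'
#' Produced by [generateCountField()]. Background tiles carry Poisson counts;
#' planted hotspot tiles carry counts from a shifted distribution strictly
#' above the background mean.
#'
#' @slot counts integer matrix (rows x cols) of per-tile bud counts.
#' @slot plantedHotspots list of integer matrices, each n x 2 (row, col) of
#'   one planted hotspot block.
#' @slot backgroundMean numeric(1).
#' @slot hotspotShift numeric(1).
#' @slot seed integer(1).
#'
#' @export
setClass("SyntheticCountField",
  representation(counts = "matrix", plantedHotspots = "list",
                 backgroundMean = "numeric", hotspotShift = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@counts < 0)) return("counts must be non-negative")
    for (h in object@plantedHotspots) {
      v <- object@counts[cbind(h[, 1], h[, 2])]
      if (any(v <= object@backgroundMean))
        return("planted hotspot counts must exceed the background mean")
    }
    TRUE
  })

#' StainMaps: per-pixel optical-density maps after color deconvolution
#'
#' @slot dab numeric matrix of DAB optical density (>= 0).
#' @slot hematoxylin numeric matrix of hematoxylin optical density (>= 0).
#' @slot residual numeric matrix of residual-channel density (>= 0).
#' @slot stainMatrix 3 x 3 matrix of unit stain vectors (rows H, DAB, residual).
#'
#' @export
setClass("StainMaps",
  representation(dab = "matrix", hematoxylin = "matrix",
                 residual = "matrix", stainMatrix = "matrix"),
  validity = function(object) {
    d <- dim(object@dab)
    if (!identical(d, dim(object@hematoxylin)) ||
        !identical(d, dim(object@residual)))
      return("density maps must share one shape")
    if (min(object@dab) < 0 || min(object@hematoxylin) < 0 ||
        min(object@residual) < 0)
      return("densities must be non-negative")
    TRUE
  })

#' ForegroundMask: binary DAB-positive mask with threshold metadata
#'
#' @slot mask logical matrix, TRUE = foreground (DAB-positive).
#' @slot centers numeric(2), the two k-means cluster centers (low, high);
#'   `NA` when the input map was constant.
#'
#' @export
setClass("ForegroundMask",
  representation(mask = "matrix", centers = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    TRUE
  })

#' ObjectSet: measured, classified connected tissue objects
#'
#' One row per detected object with measurements in pixel and micron units,
#' the size class from the bud area gate (300-3125 px), and the final label
#' once a morphology classifier has run. The label matrix maps every
#' foreground pixel to its object id.
#'
#' @slot objects data.frame with columns `id`, `row`, `col` (centroid),
#'   `area_px`, `area_um2`, `perimeter_px`, `bbox_r0`, `bbox_c0`, `bbox_r1`,
#'   `bbox_c1` (half-open, 0-based), `size_class`
#'   (debris/bud_candidate/islet_or_mass), `touches_edge`, `final_label`
#'   (bud/not_bud/mass or NA).
#' @slot labels integer matrix, object id per pixel (0 = background).
#' @slot pixelAreaUm2 numeric(1).
#'
#' @export
setClass("ObjectSet",
  representation(objects = "data.frame", labels = "matrix",
                 pixelAreaUm2 = "numeric"),
  validity = function(object) {
    df <- object@objects
    need <- c("id", "row", "col", "area_px", "area_um2", "perimeter_px",
              "bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1", "size_class",
              "touches_edge", "final_label")
    if (!all(need %in% names(df)))
      return(paste("objects table lacks columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
    if (nrow(df) > 0) {
      if (any(abs(df$area_um2 - df$area_px * object@pixelAreaUm2) > 1e-8))
        return("area_um2 must equal area_px * pixelAreaUm2")
      gate <- df$area_px >= 300 & df$area_px <= 3125
      if (any((df$size_class == "bud_candidate") != gate))
        return("bud_candidate class must match the [300, 3125] px gate")
    }
    TRUE
  })

#' NeighborGraph: Delaunay neighborhood of object centroids
#'
#' @slot edges data.frame with `from`, `to` (object ids) and `distance_px`;
#'   symmetric edges stored once with from < to.
#' @slot nnDistance named numeric, nearest-neighbor distance per object id.
#' @slot degenerate logical(1), TRUE when the triangulation fell back to the
#'   complete graph (fewer than 3 objects or collinear centroids).
#'
#' @export
setClass("NeighborGraph",
  representation(edges = "data.frame", nnDistance = "numeric",
                 degenerate = "logical"))

#' TileGrid: virtual-TMA lattice over a region of interest
#'
#' Grid points spaced `spacing` px apart inside the ROI polygon; every point
#' is the center of one square virtual core of side `tileSide` px (the
#' default side is twice the spacing, i.e. 50% overlap between neighbors).
#'
#' @slot tiles data.frame with `row_idx`, `col_idx` (lattice indices),
#'   `center_x`, `center_y` (pixel coordinates), and once counted `n_buds`
#'   and `grade`.
#' @slot spacing numeric(1) grid-point distance in px (default 1800).
#' @slot tileSide numeric(1) core side in px (default 3600).
#' @slot roi numeric matrix (n x 2) ROI polygon.
#'
#' @export
setClass("TileGrid",
  representation(tiles = "data.frame", spacing = "numeric",
                 tileSide = "numeric", roi = "matrix"),
  validity = function(object) {
    if (object@spacing <= 0 || object@tileSide <= 0)
      return("spacing and tileSide must be positive")
    TRUE
  })

#' ZScoreMap: standardized per-tile statistic
#'
#' @slot tiles data.frame with `row_idx`, `col_idx`, `value`, `z`.
#' @slot mu numeric(1) slide mean.
#' @slot sigma numeric(1) slide population standard deviation.
#' @slot threshold numeric(1) hotspot threshold z* (default 1.67).
#'
#' @export
setClass("ZScoreMap",
  representation(tiles = "data.frame", mu = "numeric", sigma = "numeric",
                 threshold = "numeric"))

#' HotspotResult: significant tiles grouped into spatially separated hotspots
#'
#' @slot tiles data.frame with `row_idx`, `col_idx`, `z`, `significant`,
#'   `hotspot` (hotspot id, 0 = none).
#' @slot nHotspots integer(1) count of spatially separated hotspots.
#' @slot nHotspotsNormalized numeric(1), `nHotspots / n tiles analyzed`.
#' @slot summary data.frame per hotspot: `hotspot`, `n_tiles`, `peak_value`.
#' @slot threshold numeric(1).
#'
#' @export
setClass("HotspotResult",
  representation(tiles = "data.frame", nHotspots = "integer",
                 nHotspotsNormalized = "numeric", summary = "data.frame",
                 threshold = "numeric"))

#' MatchReport: detections versus ground truth by bounding-box overlap
#'
#' @slot pairs data.frame of matches: `detection`, `truth`, `iou`, `type`
#'   (correct/double).
#' @slot rates named numeric with `correct_positive_rate`,
#'   `false_positive_rate`, `false_negative_rate`, `double_detection_rate`,
#'   `precision`.
#' @slot counts named numeric with `n_truth`, `n_detections`, `n_matched`,
#'   `n_false_positive`, `n_double`.
#' @slot minOverlap numeric(1) IoU acceptance threshold.
#' @slot degenerate logical(1), TRUE for the empty-truth-and-detections case.
#'
#' @export
setClass("MatchReport",
  representation(pairs = "data.frame", rates = "numeric", counts = "numeric",
                 minOverlap = "numeric", degenerate = "logical"))

#' CoreMap: detected TMA cores on one thumbnail
#'
#' @slot cores data.frame with `id` (row-major name index), `row`, `col`
#'   (centroid), `area_px`, `diameter_px` (equivalent circular diameter).
#' @slot labels integer matrix, core id per pixel.
#'
#' @export
setClass("CoreMap",
  representation(cores = "data.frame", labels = "matrix"))

#' CorePairing: similarity registration and one-to-one core pairing
#'
#' @slot scale numeric(1); @slot rotation numeric(1) radians;
#' @slot translation numeric(2) (x, y), mapping moving (IHC) coordinates
#'   into the fixed (HE) frame.
#' @slot pairs data.frame with `fixed_id`, `moving_id`, `residual_px`.
#' @slot unmatchedFixed integer vector; @slot unmatchedMoving integer vector.
#'
#' @export
setClass("CorePairing",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric", pairs = "data.frame",
                 unmatchedFixed = "integer", unmatchedMoving = "integer"))

#' BudClassifier: virtual parent of tile classifiers
#'
#' A classifier is a filter over 100 x 100 x 3 candidate tiles: it assigns a
#' bud probability and the label bud / not_bud, never changing the candidate
#' set itself.
#'
#' @export
setClass("BudClassifier", representation("VIRTUAL"))

#' RuleBudClassifier: deterministic handcrafted fallback classifier
#'
#' Accepts a tile when the central DAB-positive object is compact
#' (solidity >= `minSolidity`), not too elongated
#' (eccentricity <= `maxEccentricity`), its mean DAB density exceeds
#' `minDensity`, and its area lies in the bud gate.
#'
#' @slot minSolidity numeric(1); @slot maxEccentricity numeric(1);
#' @slot minDensity numeric(1);
#' @slot areaGate numeric(2) inclusive area gate in px.
#'
#' @export
setClass("RuleBudClassifier", contains = "BudClassifier",
  representation(minSolidity = "numeric", maxEccentricity = "numeric",
                 minDensity = "numeric", areaGate = "numeric"))

#' CNNBudClassifier: small trained convolutional network
#'
#' Eight computational layers: two blocks of 3x3 convolution + ReLU +
#' 2x2 max-pooling, then two fully connected layers with softmax output
#' over the classes bud / not bud.
#'
#' @slot weights list of layer weight arrays.
#' @slot meta list with training metadata (epochs, learning rate, seed,
#'   final training accuracy).
#'
#' @export
setClass("CNNBudClassifier", contains = "BudClassifier",
  representation(weights = "list", meta = "list"))
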