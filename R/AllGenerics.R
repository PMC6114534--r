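#' Classify candidate tiles
#'
#' Applies a classifier to a list of 100 x 100 x 3 candidate tiles and
#' returns one row per tile with the bud probability and the final label.
#' A tile is labeled `bud` when `p_bud >= threshold` (ties go to bud).
#'
#' @param model a [BudClassifier-class] object.
#' @param tiles list of tiles from [extractTiles()].
#' @param threshold decision threshold on the bud probability (default 0.5).
#' @return data.frame with `id`, `p_bud`, `label` (bud / not_bud).
#' @export
setGeneric("classifyTiles", function(model, tiles, threshold = 0.5)
  standardGeneric("classifyTiles"))

#' @describeIn ObjectSet-class Number of objects in the set.
#' @param x,object an `ObjectSet`.
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @describeIn ObjectSet-class The per-object measurement table.
#' @export
setGeneric("objTable", function(x) standardGeneric("objTable"))

#' @describeIn ObjectSet-class The object-id label matrix.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @describeIn ObjectSet-class Rows of the table with size class
#'   `bud_candidate` that do not touch the image edge.
#' @export
setGeneric("budCandidates", function(x) standardGeneric("budCandidates"))

#' @describeIn ObjectSet-class Rows with final label `bud`.
#' @export
setGeneric("buds", function(x) standardGeneric("buds"))

#' @describeIn TileGrid-class Per-tile table.
#' @param x a `TileGrid`.
#' @export
setGeneric("tileTable", function(x) standardGeneric("tileTable"))

#' @describeIn TileGrid-class Number of tiles.
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

setMethod("nObjects", "ObjectSet", function(x) nrow(x@objects))
setMethod("objTable", "ObjectSet", function(x) x@objects)
setMethod("labelMatrix", "ObjectSet", function(x) x@labels)
setMethod("budCandidates", "ObjectSet", function(x)
  x@objects[x@objects$size_class == "bud_candidate" & !x@objects$touches_edge, ,
            drop = FALSE])
setMethod("buds", "ObjectSet", function(x)
  x@objects[!is.na(x@objects$final_label) & x@objects$final_label == "bud", ,
            drop = FALSE])

setMethod("tileTable", "TileGrid", function(x) x@tiles)
setMethod("nTiles", "TileGrid", function(x) nrow(x@tiles))

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticScene %d x %d px (%.2f um2/px), seed %d\n",
              d[1], d[2], object@pixelAreaUm2, object@seed))
  if (nrow(object@truth))
    print(table(object@truth$label))
  else cat("  pure background (no planted objects)\n")
})

setMethod("show", "ObjectSet", function(object) {
  cat(sprintf("ObjectSet with %d objects (%.2f um2/px)\n",
              nrow(object@objects), object@pixelAreaUm2))
  if (nrow(object@objects)) print(table(object@objects$size_class))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d virtual cores, spacing %g px, side %g px\n",
              nrow(object@tiles), object@spacing, object@tileSide))
})

setMethod("show", "ZScoreMap", function(object) {
  cat(sprintf("ZScoreMap over %d tiles: mu = %.3f, sigma = %.3f, z* = %.2f\n",
              nrow(object@tiles), object@mu, object@sigma, object@threshold))
})

setMethod("show", "HotspotResult", function(object) {
  cat(sprintf(
    "HotspotResult: %d significant tile(s), %d hotspot(s) (%.4f per tile)\n",
    sum(object@tiles$significant), object@nHotspots,
    object@nHotspotsNormalized))
})

setMethod("show", "MatchReport", function(object) {
  r <- object@rates
  cat(sprintf(
    "MatchReport: CPR %.3f, FPR %.3f, FNR %.3f, DDR %.3f, precision %.3f\n",
    r["correct_positive_rate"], r["false_positive_rate"],
    r["false_negative_rate"], r["double_detection_rate"], r["precision"]))
})

setMethod("show", "CorePairing", function(object) {
  cat(sprintf(
    "CorePairing: scale %.4f, rotation %.3f deg, %d pair(s), %d+%d unmatched\n",
    object@scale, object@rotation * 180 / pi, nrow(object@pairs),
    length(object@unmatchedFixed), length(object@unmatchedMoving)))
})

setMethod("show", "RuleBudClassifier", function(object) {
  cat(sprintf(
    "RuleBudClassifier: solidity >= %.2f, eccentricity <= %.2f, density > %.2f, area in [%g, %g] px\n",
    object@minSolidity, object@maxEccentricity, object@minDensity,
    object@areaGate[1], object@areaGate[2]))
})

setMethod("show", "CNNBudClassifier", function(object) {
  cat(sprintf(
    "CNNBudClassifier: %d layers, trained %d epoch(s), final accuracy %.3f\n",
    length(object@weights), object@meta$epochs, object@meta$accuracy))
})
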