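#' Pipeline configuration
#'
#' All tunables of the detection and analysis pipeline in one list that
#' round-trips losslessly through YAML ([writeConfig()], [readConfig()]).
#' Defaults equal the published values where the source prints them: bud
#' area gate 300-3125 px (72-750 um2 at 0.24 um2/px), virtual-core grid
#' spacing 1800 px with core side 3600 px, hotspot threshold z* = 1.67,
#' classifier tile 100 x 100 x 3. The remaining knobs (clustering distances
#' and tolerances, mask cleanup sizes, classifier choice) are documented
#' package defaults.
#'
#' @param ... named overrides of any default.
#' @return a list of class `budConfig`.
#' @export
budConfig <- function(...) {
  cfg <- list(
    pixel_area_um2 = 0.24,
    area_gate_px = c(300, 3125),
    min_speck_px = 10,
    fill_holes_px = 50,
    merge_distance_px = 50,
    merge_rel_tolerance = 0.2,
    border_distance_px = 25,
    tile_spacing_px = 1800,
    tile_side_px = 3600,
    z_threshold = 1.67,
    grading_scheme = "satoh",
    grading_boundary = "lower",
    classifier = "rules",
    classifier_threshold = 0.5,
    classifier_tile_px = 100,
    reinhard = FALSE,
    seed = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "budConfig"
  cfg
}

#' @rdname budConfig
#' @param config a `budConfig`; @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname budConfig
#' @export
readConfig <- function(path) {
  do.call(budConfig, yaml::read_yaml(path))
}

#' Detect tumor buds in a pan-cytokeratin IHC image
#'
#' The full detection cascade: color deconvolution of the DAB channel,
#' k-means binarization with mask cleanup, 8-connected component labeling
#' with the bud size gate, recombination of equal-morphology neighbors,
#' absorption of fragments into nearby masses, and a final morphology check
#' of each remaining candidate through the configured classifier (the
#' deterministic rule classifier by default, or a trained
#' [CNNBudClassifier-class]).
#'
#' @param image RGB array in 0..255, or a [SyntheticScene-class].
#' @param config a [budConfig()].
#' @param classifier optional [BudClassifier-class] overriding the config.
#' @param referenceStats optional [reinhardStats()] of a reference image;
#'   applied before detection when `config$reinhard` is TRUE.
#' @return list with `objects` (the final [ObjectSet-class], `final_label`
#'   filled), `detections` (data.frame of bud rows), `mask`
#'   (the [ForegroundMask-class]) and `stains` ([StainMaps-class]).
#' @export
detectBuds <- function(image, config = budConfig(), classifier = NULL,
                       referenceStats = NULL) {
  if (is(image, "SyntheticScene")) image <- image@image
  if (isTRUE(config$reinhard)) {
    if (is.null(referenceStats))
      stop("reinhard normalization requested but no reference statistics")
    image <- reinhardNormalize(image, referenceStats)
  }
  stains <- colorDeconvolve(image)
  mask <- binarizeKmeans(stains@dab, minSpeckPx = config$min_speck_px,
                         fillHolesPx = config$fill_holes_px)
  objs <- labelComponents(mask, pixelAreaUm2 = config$pixel_area_um2)
  objs <- mergeSimilar(objs, distancePx = config$merge_distance_px,
                       relTolerance = config$merge_rel_tolerance)
  objs <- absorbIntoMass(objs, borderDistancePx = config$border_distance_px)
  df <- objs@objects
  df$final_label[df$size_class == "islet_or_mass"] <- "mass"
  df$final_label[df$size_class == "debris"] <- "not_bud"
  cand <- budCandidates(objs)
  df$final_label[df$size_class == "bud_candidate" & df$touches_edge] <-
    "not_bud"
  if (nrow(cand)) {
    if (is.null(classifier)) {
      classifier <- if (identical(config$classifier, "rules"))
        ruleBudClassifier(areaGate = config$area_gate_px)
      else stop("no trained classifier supplied")
    }
    tiles <- extractTiles(image, cand, side = config$classifier_tile_px)
    verdict <- classifyTiles(classifier, tiles,
                             threshold = config$classifier_threshold)
    df$final_label[match(verdict$id, df$id)] <- verdict$label
  }
  objs@objects <- df
  list(objects = objs, detections = df[!is.na(df$final_label) &
                                         df$final_label == "bud", ,
                                       drop = FALSE],
       mask = mask, stains = stains)
}
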