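#' Z-score map of a per-tile statistic
#'
#' Standardizes every tile value against the slide's own distribution:
#' `z = (x - mu) / sigma` with the mean and the population (1/N) standard
#' deviation taken over all tiles of the slide. With zero spread all z are
#' set to 0 with a warning.
#'
#' @param grid a [TileGrid-class] with counts, a [SyntheticCountField-class],
#'   or a data.frame with `row_idx`, `col_idx` and the statistic column.
#' @param statistic name of the tile statistic column (default `n_buds`).
#' @param threshold hotspot threshold carried into downstream calls
#'   (default 1.67).
#' @return a [ZScoreMap-class]; errors with fewer than two tiles.
#' @export
zscoreMap <- function(grid, statistic = "n_buds", threshold = 1.67) {
  tiles <- if (is(grid, "TileGrid")) grid@tiles
    else if (is(grid, "SyntheticCountField")) {
      cf <- grid
      data.frame(row_idx = as.vector(row(cf@counts)),
                 col_idx = as.vector(col(cf@counts)),
                 n_buds = as.vector(cf@counts))
    } else grid
  if (!statistic %in% names(tiles))
    stop(sprintf("no '%s' column on the tiles", statistic))
  x <- tiles[[statistic]]
  if (length(x) < 2L) stop("need at least two tiles to standardize")
  if (anyNA(x)) stop("tile statistic contains NA; count buds first")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    warning("zero spread across tiles; all z-scores set to 0")
    z <- rep(0, length(x))
  } else z <- (x - mu) / sigma
  new("ZScoreMap",
      tiles = data.frame(row_idx = tiles$row_idx, col_idx = tiles$col_idx,
                         value = x, z = z),
      mu = mu, sigma = sigma, threshold = threshold)
}

#' Segment and count significant budding hotspots
#'
#' Tiles with `z > threshold` (strict) are significant; maximal
#' 8-connected sets of significant tiles on the (row, col) lattice form the
#' hotspots. Two significant regions separated by non-significant tiles
#' count as two hotspots; contiguous significant tiles collapse into one.
#' The normalized count divides by the number of analyzed tiles.
#'
#' @param zmap a [ZScoreMap-class].
#' @param threshold override of the z* threshold (default: the map's).
#' @param connectivity 8 (default) or 4.
#' @return a [HotspotResult-class].
#' @export
findHotspots <- function(zmap, threshold = zmap@threshold, connectivity = 8) {
  tiles <- zmap@tiles
  sig <- tiles$z > threshold
  hot <- integer(nrow(tiles))
  nHot <- 0L
  if (any(sig)) {
    key <- paste(tiles$row_idx, tiles$col_idx)
    sigIdx <- which(sig)
    lookup <- stats::setNames(seq_along(sigIdx), key[sigIdx])
    offs <- if (connectivity == 8)
      cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    comp <- integer(length(sigIdx))
    for (s in seq_along(sigIdx)) {
      if (comp[s] != 0L) next
      nHot <- nHot + 1L
      queue <- s
      comp[s] <- nHot
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        r <- tiles$row_idx[sigIdx[cur]]; cc <- tiles$col_idx[sigIdx[cur]]
        nb <- lookup[paste(r + offs[, 1], cc + offs[, 2])]
        nb <- nb[!is.na(nb)]
        new <- nb[comp[nb] == 0L]
        comp[new] <- nHot
        queue <- c(queue, new)
      }
    }
    hot[sigIdx] <- comp
  }
  tiles$significant <- sig
  tiles$hotspot <- hot
  summ <- if (nHot > 0) {
    do.call(rbind, lapply(seq_len(nHot), function(h) {
      sel <- hot == h
      data.frame(hotspot = h, n_tiles = sum(sel),
                 peak_value = max(tiles$value[sel]))
    }))
  } else data.frame(hotspot = integer(), n_tiles = integer(),
                    peak_value = numeric())
  new("HotspotResult", tiles = tiles, nHotspots = nHot,
      nHotspotsNormalized = nHot / nrow(tiles), summary = summ,
      threshold = threshold)
}

#' Normalized Shannon entropy of tile categories
#'
#' Shannon entropy (in bits) of the distribution of tile categories (e.g.
#' budding grades), normalized either by `log2(nCategories)` (default: 1 at
#' the uniform distribution over all categories) or by `log2(n)` with n the
#' number of tiles (`normalize = "samples"`).
#'
#' @param values vector of tile categories (integers or factor levels).
#' @param nCategories number of possible categories (>= 2).
#' @param normalize `"categories"` (default) or `"samples"`.
#' @return list with `p` (category probabilities), `H_bits`,
#'   `normalizer` and `normalized` in `[0, 1]`.
#' @export
normalizedEntropy <- function(values, nCategories,
                              normalize = c("categories", "samples")) {
  normalize <- match.arg(normalize)
  if (nCategories < 2) stop("need at least two categories")
  if (!length(values)) stop("need at least one value")
  p <- as.vector(table(values)) / length(values)
  H <- -sum(p * log2(p))
  nrm <- if (normalize == "categories") log2(nCategories)
         else log2(max(length(values), 2))
  list(p = p, H_bits = H, normalizer = nrm,
       normalized = min(H / nrm, 1))
}

#' Histogram split into measurements inside/outside the normal distribution
#'
#' Negative-control analysis without spatial information: tiles are split by
#' the same `z > threshold` rule as [findHotspots()], and the significant
#' ("outside the normal distribution") set is summarized by its normalized
#' size and the median and maximum tile value.
#'
#' @param zmap a [ZScoreMap-class].
#' @param threshold z* threshold (default: the map's).
#' @return list with `n_significant`, `n_significant_normalized`,
#'   `median_value`, `max_value` and `empty` (TRUE when no tile is
#'   significant; the medians are then NA).
#' @export
histogramOutsideDistribution <- function(zmap, threshold = zmap@threshold) {
  tiles <- zmap@tiles
  sig <- tiles$z > threshold
  if (!any(sig)) {
    return(list(n_significant = 0L, n_significant_normalized = 0,
                median_value = NA_real_, max_value = NA_real_, empty = TRUE))
  }
  v <- tiles$value[sig]
  list(n_significant = sum(sig),
       n_significant_normalized = sum(sig) / nrow(tiles),
       median_value = stats::median(v), max_value = max(v), empty = FALSE)
}
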