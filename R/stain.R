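#' Standard H-DAB stain matrix
#'
#' Unit optical-density vectors for hematoxylin, DAB and the residual
#' channel (rows, in RGB order), using the classical Ruifrok-Johnston
#' values for the H-DAB combination. The residual vector is the normalized
#' cross product of the first two, completing an invertible basis.
#'
#' @return 3 x 3 numeric matrix with unit rows, rownames
#'   `hematoxylin`, `dab`, `residual`.
#' @export
hdabStainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

## Optical density of 8-bit intensities: OD = -log10((I + 1) / 256).
opticalDensity <- function(i) -log10((i + 1) / 256)

## Inverse: 8-bit intensity from optical density (not rounded).
intensityFromOD <- function(od) 256 * 10^(-od) - 1

#' Render stain density maps as an RGB image
#'
#' Forward model of [colorDeconvolve()]: per-pixel stain densities are mixed
#' through the stain matrix in optical-density space and converted back to
#' 8-bit intensities. Used by the synthetic-scene generator, and by tests to
#' check the unmixing round trip.
#'
#' @param hematoxylin,dab,residual numeric matrices (one shape) of stain
#'   densities; `residual` defaults to zero.
#' @param stainMatrix 3 x 3 unit stain matrix, rows H / DAB / residual.
#' @param round round intensities to integers (default TRUE).
#' @return numeric array height x width x 3 in 0..255.
#' @export
renderDensities <- function(hematoxylin, dab, residual = NULL,
                            stainMatrix = hdabStainMatrix(), round = TRUE) {
  if (is.null(residual)) residual <- matrix(0, nrow(dab), ncol(dab))
  stopifnot(identical(dim(hematoxylin), dim(dab)),
            identical(dim(residual), dim(dab)))
  dens <- cbind(as.vector(hematoxylin), as.vector(dab), as.vector(residual))
  od <- dens %*% stainMatrix
  img <- intensityFromOD(od)
  img <- pmin(pmax(img, 0), 255)
  if (round) img <- round(img)
  array(img, dim = c(nrow(dab), ncol(dab), 3L))
}

#' Separate stains by color deconvolution in optical-density space
#'
#' Converts an 8-bit RGB image to per-channel optical density
#' `OD = -log10((I + 1) / 256)` and unmixes it with the inverse stain
#' matrix. Negative unmixed densities are clipped to zero. For a pure-white
#' image all densities are zero.
#'
#' @param image numeric array height x width x 3 with values in 0..255.
#' @param stainMatrix 3 x 3 matrix of unit stain vectors (rows hematoxylin,
#'   DAB, residual); must be non-singular.
#' @return a [StainMaps-class] object.
#' @export
colorDeconvolve <- function(image, stainMatrix = hdabStainMatrix()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  rn <- sqrt(rowSums(stainMatrix^2))
  if (any(abs(rn - 1) > 1e-6))
    stop("stain matrix rows must be unit-norm")
  dt <- det(stainMatrix)
  if (abs(dt) < 1e-8) stop("stain matrix is singular")
  d <- dim(image)
  od <- opticalDensity(matrix(image, d[1] * d[2], 3L))
  dens <- od %*% solve(stainMatrix)
  dens[dens < 0] <- 0
  new("StainMaps",
      hematoxylin = matrix(dens[, 1], d[1], d[2]),
      dab = matrix(dens[, 2], d[1], d[2]),
      residual = matrix(dens[, 3], d[1], d[2]),
      stainMatrix = stainMatrix)
}

#' Binarize a DAB density map by 2-means clustering
#'
#' Two-class k-means on the per-pixel DAB density, initialized
#' deterministically at the density minimum and maximum; the cluster with
#' the higher center is foreground. The resulting mask is cleaned by
#' removing foreground specks below `minSpeckPx` and filling enclosed
#' background holes below `fillHolesPx` so that object areas near the
#' 300 px bud gate are stable.
#'
#' @param density numeric matrix of DAB optical densities.
#' @param minSpeckPx remove foreground components smaller than this (px).
#' @param fillHolesPx fill enclosed background holes smaller than this (px).
#' @param minRange density range below which the map is treated as constant
#'   (default 0.1 OD); quantization of 8-bit images leaves a spread of about
#'   0.01 OD on unstained tissue, well under this guard.
#' @return a [ForegroundMask-class]; empty (with a warning) for a constant
#'   density map.
#' @export
binarizeKmeans <- function(density, minSpeckPx = 10, fillHolesPx = 50,
                           minRange = 0.1) {
  stopifnot(is.matrix(density))
  lo <- min(density); hi <- max(density)
  if (hi - lo < minRange) {
    warning("constant density map: no foreground found")
    return(new("ForegroundMask",
               mask = matrix(FALSE, nrow(density), ncol(density)),
               centers = c(NA_real_, NA_real_)))
  }
  km <- stats::kmeans(as.vector(density), centers = matrix(c(lo, hi), 2, 1),
                      algorithm = "Lloyd", iter.max = 100L)
  fg <- which.max(km$centers[, 1])
  mask <- matrix(km$cluster == fg, nrow(density), ncol(density))
  mask <- cleanMask(mask, minSpeckPx, fillHolesPx)
  new("ForegroundMask", mask = mask,
      centers = sort(as.vector(km$centers)))
}

## Remove sub-threshold specks and fill small enclosed holes.
cleanMask <- function(mask, minSpeckPx, fillHolesPx) {
  if (minSpeckPx > 0 && any(mask)) {
    lab <- label8(mask)
    sz <- tabulate(lab[lab > 0L])
    drop <- which(sz < minSpeckPx)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  if (fillHolesPx > 0 && any(mask) && !all(mask)) {
    bg <- EBImage::bwlabel(matrix(as.numeric(!mask), nrow(mask)))
    bg <- matrix(as.integer(bg), nrow(mask))
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    sz <- tabulate(bg[bg > 0L])
    fill <- setdiff(which(sz < fillHolesPx), border)
    if (length(fill)) mask[bg %in% fill] <- TRUE
  }
  mask
}

## Ruderman log-LMS (l-alpha-beta) color space transforms for Reinhard
## normalization.
.rgb2lms <- rbind(c(0.3811, 0.5783, 0.0402),
                  c(0.1967, 0.7244, 0.0782),
                  c(0.0241, 0.1288, 0.8444))
.lms2lab1 <- rbind(c(1, 1, 1), c(1, 1, -2), c(1, -1, 0))
.labScale <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2)))

rgbToLab <- function(image) {
  d <- dim(image)
  rgb <- matrix(image, d[1] * d[2], 3L) / 255
  lms <- rgb %*% t(.rgb2lms)
  lms[lms < 1e-6] <- 1e-6
  log10(lms) %*% t(.labScale %*% .lms2lab1)
}

labToRgb <- function(lab, dims) {
  lms <- 10^(lab %*% t(solve(.labScale %*% .lms2lab1)))
  rgb <- lms %*% t(solve(.rgb2lms)) * 255
  rgb <- pmin(pmax(rgb, 0), 255)
  array(rgb, dim = c(dims[1], dims[2], 3L))
}

#' Per-channel color statistics in the Reinhard (log-LMS) space
#'
#' @param image RGB array in 0..255.
#' @return list with numeric vectors `mean` and `sd` (length 3).
#' @export
reinhardStats <- function(image) {
  lab <- rgbToLab(image)
  list(mean = colMeans(lab), sd = apply(lab, 2, stats::sd))
}

#' Reinhard stain normalization
#'
#' Transfers the per-channel mean and standard deviation of the image, in
#' the decorrelated log-LMS color space, to the reference statistics:
#' `(x - mu_src) / sd_src * sd_ref + mu_ref`, then converts back to RGB and
#' clips to 0..255. A channel with zero source spread is passed through
#' unchanged with a warning. The detection pipeline default is no
#' normalization; this is available behind a flag for slides from a
#' different staining batch.
#'
#' @param image RGB array in 0..255.
#' @param referenceStats list with `mean` and `sd` as from [reinhardStats()].
#' @return normalized RGB array (same shape).
#' @export
reinhardNormalize <- function(image, referenceStats) {
  lab <- rgbToLab(image)
  mu <- colMeans(lab); s <- apply(lab, 2, stats::sd)
  for (ch in 1:3) {
    if (s[ch] < 1e-12) {
      ## zero spread: the channel carries no contrast to rescale; recenter
      ## it at the reference mean so a constant image maps to the reference
      warning(sprintf("channel %d has zero spread; recentered only", ch))
      lab[, ch] <- referenceStats$mean[ch]
    } else {
      lab[, ch] <- (lab[, ch] - mu[ch]) / s[ch] * referenceStats$sd[ch] +
        referenceStats$mean[ch]
    }
  }
  labToRgb(lab, dim(image))
}
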