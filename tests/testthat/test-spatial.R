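test_that("z-scores use the population standard deviation", {
  counts <- c(2, 4, 4, 4, 5, 5, 7, 9)
  tiles <- data.frame(row_idx = 1:8, col_idx = 1L, n_buds = counts)
  zm <- zscoreMap(tiles)
  expect_equal(zm@mu, 5)
  expect_equal(zm@sigma, 2)                 # population sd, not sample sd
  expect_equal(zm@tiles$z, (counts - 5) / 2)
  expect_equal(zm@tiles$z, oracleZ(counts))
})

test_that("degenerate inputs to zscoreMap behave as documented", {
  one <- data.frame(row_idx = 1L, col_idx = 1L, n_buds = 3)
  expect_error(zscoreMap(one), "two tiles")
  flat <- data.frame(row_idx = 1:4, col_idx = 1L, n_buds = rep(2, 4))
  expect_warning(zf <- zscoreMap(flat), "zero spread")
  expect_true(all(zf@tiles$z == 0))
  nas <- data.frame(row_idx = 1:4, col_idx = 1L, n_buds = c(1, NA, 2, 3))
  expect_error(zscoreMap(nas), "NA")
  expect_error(zscoreMap(flat, statistic = "missing"), "missing")
})

test_that("zscoreMap accepts TileGrid and SyntheticCountField inputs", {
  cf <- generateCountField(6, 6, 4, list(rbind(c(2, 2))), 20, seed = 8)
  zm <- zscoreMap(cf)
  expect_equal(zm@tiles$value, as.vector(cf@counts))
  expect_equal(zm@tiles$z, oracleZ(as.vector(cf@counts)))
  roi <- rectPolygon(0, 0, 9000, 9000)
  g <- countBudsPerTile(makeGrid(roi, 1800),
                        data.frame(x = runif(30, 0, 9000),
                                   y = runif(30, 0, 9000)))
  zg <- zscoreMap(g)
  expect_equal(nrow(zg@tiles), nTiles(g))
})

test_that("hotspot segmentation merges 8-connected significant tiles", {
  ## hand-built z pattern on a 5 x 5 lattice
  tiles <- expand.grid(row_idx = 1:5, col_idx = 1:5)
  tiles$n_buds <- 0
  hotA <- (tiles$row_idx %in% 1:2 & tiles$col_idx %in% 1:2)   # 2x2 block
  hotB <- (tiles$row_idx == 5 & tiles$col_idx == 5)           # far corner
  tiles$n_buds[hotA] <- 30
  tiles$n_buds[hotB] <- 30
  hs <- findHotspots(zscoreMap(tiles))
  expect_equal(hs@nHotspots, 2L)
  expect_equal(hs@nHotspotsNormalized, 2 / 25)
  expect_setequal(hs@summary$n_tiles, c(4L, 1L))
  expect_equal(hs@summary$peak_value, c(30, 30))
  ## diagonal contact: make (3,3) significant, touching block A at (2,2)
  tiles2 <- tiles
  tiles2$n_buds[tiles2$row_idx == 3 & tiles2$col_idx == 3] <- 30
  hs8 <- findHotspots(zscoreMap(tiles2))
  expect_equal(hs8@nHotspots, 2L)           # merges with the 2x2 block
  hs4 <- findHotspots(zscoreMap(tiles2), connectivity = 4)
  expect_equal(hs4@nHotspots, 3L)           # separate under 4-connectivity
})

test_that("hotspot counts match the flood-fill oracle on random fields", {
  set.seed(33)
  for (i in 1:25) {
    nr <- sample(3:9, 1); nc <- sample(3:9, 1)
    counts <- matrix(rpois(nr * nc, 3), nr, nc)
    tiles <- data.frame(row_idx = as.vector(row(counts)),
                        col_idx = as.vector(col(counts)),
                        n_buds = as.vector(counts))
    if (stats::sd(tiles$n_buds) == 0) next
    zm <- zscoreMap(tiles)
    hs <- findHotspots(zm)
    sig <- matrix(matrix(zm@tiles$z, nr, nc) > 1.67, nr, nc)
    expect_equal(hs@nHotspots, oracleFloodCount(sig))
  }
})

test_that("the threshold is strict and raising it never adds hotspots", {
  tiles <- data.frame(row_idx = 1:10, col_idx = 1L,
                      n_buds = c(rep(0, 9), 10))
  zm <- zscoreMap(tiles)
  zTop <- max(zm@tiles$z)
  ## at exactly z the tile is NOT significant (strict inequality)
  expect_equal(findHotspots(zm, threshold = zTop)@nHotspots, 0L)
  expect_equal(findHotspots(zm, threshold = zTop - 1e-9)@nHotspots, 1L)
})

test_that("entropy closed forms hold", {
  ## uniform over 4 categories: H = 2 bits, normalized 1
  e <- normalizedEntropy(rep(1:4, each = 5), nCategories = 4)
  expect_equal(e$H_bits, 2)
  expect_equal(e$normalized, 1)
  ## single category: H = 0
  e0 <- normalizedEntropy(rep(2L, 10), nCategories = 5)
  expect_equal(e0$H_bits, 0)
  expect_equal(e0$normalized, 0)
  ## two categories p = (0.25, 0.75): H = 2 - 0.75*log2(3)
  e2 <- normalizedEntropy(c(1, 2, 2, 2), nCategories = 2)
  expect_equal(e2$H_bits, 2 - 0.75 * log2(3), tolerance = 1e-12)
  expect_equal(e2$normalized, e2$H_bits / 1, tolerance = 1e-12)
  ## sample normalization uses log2(n)
  es <- normalizedEntropy(c(1, 2, 2, 2), nCategories = 2,
                          normalize = "samples")
  expect_equal(es$normalizer, 2)
  expect_equal(es$normalized, es$H_bits / 2, tolerance = 1e-12)
  expect_error(normalizedEntropy(1:3, nCategories = 1), "two categories")
  expect_error(normalizedEntropy(integer(), 4), "one value")
})

test_that("the histogram summary agrees with the hotspot significance set", {
  cf <- generateCountField(8, 8, 3,
                           list(rbind(c(2, 2), c(2, 3), c(3, 2), c(3, 3))),
                           15, seed = 5)
  zm <- zscoreMap(cf)
  hs <- findHotspots(zm)
  hg <- histogramOutsideDistribution(zm)
  expect_equal(hg$n_significant, sum(hs@tiles$significant))
  expect_equal(hg$n_significant_normalized, hg$n_significant / 64)
  expect_equal(hg$max_value, max(zm@tiles$value[hs@tiles$significant]))
  expect_false(hg$empty)
  ## flat field: nothing outside the distribution
  flatTiles <- data.frame(row_idx = 1:5, col_idx = 1L,
                          n_buds = c(1, 1, 1, 1, 2))
  hgEmpty <- histogramOutsideDistribution(zscoreMap(flatTiles),
                                          threshold = 10)
  expect_true(hgEmpty$empty)
  expect_equal(hgEmpty$n_significant, 0L)
  expect_true(is.na(hgEmpty$median_value))
})
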