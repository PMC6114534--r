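test_that("a filled square is measured exactly", {
  m <- maskWithRect(100, 100, 21, 31, 20, 20)
  os <- labelComponents(m, pixelAreaUm2 = 0.24)
  expect_equal(nObjects(os), 1L)
  df <- objTable(os)
  expect_equal(df$area_px, 400)
  expect_equal(df$area_um2, 96)
  expect_equal(df$size_class, "bud_candidate")
  expect_equal(df$row, mean(21:40))
  expect_equal(df$col, mean(31:50))
  ## boundary pixel count of a 20x20 square: 4*20 - 4
  expect_equal(df$perimeter_px, 76)
  ## half-open 0-based bounding box
  expect_equal(unlist(df[c("bbox_r0", "bbox_c0", "bbox_r1", "bbox_c1")],
                      use.names = FALSE), c(20, 30, 40, 50))
  expect_false(df$touches_edge)
})

test_that("the size gate assigns the documented classes at the boundaries", {
  expect_equal(sizeClass(c(1, 299, 300, 3125, 3126, 10000)),
               c("debris", "debris", "bud_candidate", "bud_candidate",
                 "islet_or_mass", "islet_or_mass"))
  m <- maskWithRect(200, 200, 5, 5, 10, 10)           # 100 px -> debris
  m[100:159, 100:159] <- TRUE                          # 3600 px -> mass
  os <- labelComponents(m)
  expect_setequal(objTable(os)$size_class, c("debris", "islet_or_mass"))
})

test_that("components are 8-connected", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE                     # diagonal touch
  m[8, 8] <- TRUE                                      # far away
  os <- labelComponents(m)
  expect_equal(nObjects(os), 2L)
  expect_equal(sort(objTable(os)$area_px), c(1, 2))
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(21)
  for (i in 1:50) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    expect_equal(nObjects(labelComponents(m)), oracleFloodCount(m))
  }
})

test_that("edge-touching objects are flagged", {
  m <- maskWithRect(50, 50, 1, 10, 20, 20)
  expect_true(objTable(labelComponents(m))$touches_edge)
  m2 <- maskWithRect(50, 50, 2, 10, 20, 20)
  expect_false(objTable(labelComponents(m2))$touches_edge)
})

test_that("mergeSimilar joins nearby equal-morphology objects transitively", {
  ## two 40x40 squares, centroids 50 px apart (10 px gap), same morphology
  m <- maskWithRect(200, 200, 50, 50, 40, 40)
  m[50:89, 100:139] <- TRUE
  os <- labelComponents(m)
  expect_equal(nObjects(os), 2L)
  merged <- mergeSimilar(os, distancePx = 50, relTolerance = 0.2)
  expect_equal(nObjects(merged), 1L)
  expect_equal(objTable(merged)$area_px, 3200)
  ## transitive chain: three squares, each neighbor pair within range
  m3 <- maskWithRect(300, 300, 50, 50, 40, 40)
  m3[50:89, 100:139] <- TRUE
  m3[50:89, 150:189] <- TRUE
  expect_equal(nObjects(mergeSimilar(labelComponents(m3))), 1L)
})

test_that("mergeSimilar leaves distant or dissimilar objects alone", {
  ## far apart
  m <- maskWithRect(600, 600, 50, 50, 40, 40)
  m[500:539, 500:539] <- TRUE
  expect_equal(nObjects(mergeSimilar(labelComponents(m))), 2L)
  ## close but very different areas (40x40 = 1600 vs 20x20 = 400)
  m2 <- maskWithRect(200, 200, 50, 50, 40, 40)
  m2[60:79, 100:119] <- TRUE   # centroid distance 40, within merge range
  expect_equal(nObjects(mergeSimilar(labelComponents(m2))), 2L)
})

test_that("absorbIntoMass pulls fragments near a mass and conserves pixels", {
  ## 70x72 mass (5040 px) and a 25x24 fragment (600 px) 10 px to its right
  m <- maskWithRect(300, 300, 100, 50, 70, 72)
  m[120:144, 132:155] <- TRUE
  os <- labelComponents(m)
  expect_equal(nObjects(os), 2L)
  totalPx <- sum(objTable(os)$area_px)
  ab <- absorbIntoMass(os, borderDistancePx = 25)
  expect_equal(nObjects(ab), 1L)
  expect_equal(objTable(ab)$area_px, totalPx)
  expect_equal(objTable(ab)$size_class, "islet_or_mass")
  ## absorbing again changes nothing (fixed point)
  ab2 <- absorbIntoMass(ab, borderDistancePx = 25)
  expect_identical(objTable(ab2), objTable(ab))
})

test_that("absorbIntoMass keeps fragments beyond the border distance", {
  m <- maskWithRect(400, 400, 100, 50, 70, 72)
  m[120:144, 230:253] <- TRUE        # ~108 px away from the mass
  os <- labelComponents(m)
  ab <- absorbIntoMass(os, borderDistancePx = 25)
  expect_equal(nObjects(ab), 2L)
  ## with no mass present nothing happens
  frag <- labelComponents(maskWithRect(100, 100, 10, 10, 20, 20))
  expect_identical(objTable(absorbIntoMass(frag)), objTable(frag))
})

test_that("absorption uses boundary distance, verified against an oracle", {
  m <- maskWithRect(300, 300, 100, 50, 70, 72)
  m[120:144, 150:173] <- TRUE        # gap of 28 px: just outside radius 25
  os <- labelComponents(m)
  lab <- labelMatrix(os)
  pixA <- which(lab == 1L); pixB <- which(lab == 2L)
  d <- oracleMinDistance((pixA - 1) %% 300 + 1, (pixA - 1) %/% 300 + 1,
                         (pixB - 1) %% 300 + 1, (pixB - 1) %/% 300 + 1)
  expect_gt(d, 25)
  expect_equal(nObjects(absorbIntoMass(os, 25)), 2L)
  expect_equal(nObjects(absorbIntoMass(os, ceiling(d))), 1L)
})

test_that("the neighbor graph reproduces simple geometric cases", {
  mk <- function(pts) {
    m <- matrix(FALSE, 200, 200)
    for (k in seq_len(nrow(pts))) m[pts[k, 1], pts[k, 2]] <- TRUE
    labelComponents(m)
  }
  ## triangle: Delaunay of 3 points is the complete graph
  g3 <- buildNeighborGraph(mk(rbind(c(20, 20), c(20, 120), c(120, 20))))
  expect_equal(nrow(g3@edges), 3L)
  expect_false(g3@degenerate)
  ## unit square corners, side 100: every NN distance equals the side
  g4 <- buildNeighborGraph(mk(rbind(c(20, 20), c(20, 120),
                                    c(120, 20), c(120, 120))))
  expect_equal(unname(g4@nnDistance), rep(100, 4))
  ## one object: empty edge list, NA nearest-neighbor distance
  g1 <- buildNeighborGraph(mk(rbind(c(50, 50))))
  expect_equal(nrow(g1@edges), 0L)
  expect_true(is.na(g1@nnDistance))
  ## collinear points fall back to the complete graph with a warning
  expect_warning(
    gc <- buildNeighborGraph(mk(rbind(c(20, 20), c(20, 60), c(20, 100),
                                      c(20, 140)))),
    "degenerate")
  expect_true(gc@degenerate)
  expect_equal(nrow(gc@edges), choose(4, 2))
})
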